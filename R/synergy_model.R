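#' Fit the pathway-bridged drug-synergy model
#'
#' The top-level fitting function: assembles the selected feature blocks for
#' the labelled instances, makes a stratified train/test split with
#' train-fitted standardisation, applies the chosen imbalance correction and
#' trains a classifier (gradient-boosted trees by default). The returned
#' object carries everything needed to score new (pair, cell line)
#' instances: the fitted model, the scaler and the block selection.
#'
#' @param instances Labelled instances: data frame with `drug_a`, `drug_b`,
#'   `cell_line`, `label`.
#' @param blocks Named list of feature-block matrices (see
#'   [build_feature_blocks()]).
#' @param selection Block names to use (default: all available).
#' @param family,params Classifier configuration (see [fit_synergy()]).
#' @param strategy,ratio,k_smote Imbalance correction (see [rebalance()]).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param threshold Classification threshold for thresholded metrics.
#' @param seed Integer RNG seed governing split, resampling and training.
#' @return An object of class `synergy_model` with components `fit`,
#'   `scaler`, `selection`, `test_metrics` (an `evaluation_report`),
#'   `prevalence`, and the split sizes.
#' @export
synergy_model <- function(instances, blocks, selection = names(blocks),
                          family = "xgboost",
                          params = list(eta = 0.1, max_depth = 7, nrounds = 700),
                          strategy = c("weights", "undersample", "oversample"),
                          ratio = 2, k_smote = 5, test_fraction = 0.2,
                          threshold = 0.5, seed = 1) {
  strategy <- match.arg(strategy)
  ft <- assemble_features(instances, blocks, selection)
  sp <- split_and_scale(ft$x, ft$y, test_fraction, seed)
  rb <- rebalance(sp$train$x, sp$train$y, strategy, ratio, k_smote, seed)
  fit <- fit_synergy(rb$x, rb$y, family, params, weights = rb$weights,
                     seed = seed, block_cols = ft$block_cols)
  test_scores <- predict(fit, sp$test$x)
  structure(list(fit = fit, scaler = sp$scaler,
                 selection = names(ft$block_cols),
                 strategy = strategy, ratio = ratio,
                 threshold = threshold, seed = seed,
                 test_metrics = evaluate(sp$test$y, test_scores, threshold),
                 test_scores = test_scores, test_labels = sp$test$y,
                 prevalence = mean(ft$y),
                 n_train = length(sp$train$y), n_test = length(sp$test$y)),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat("Pathway-bridged synergy model\n")
  cat("  blocks: ", paste(x$selection, collapse = ", "), "\n", sep = "")
  cat("  classifier: ", x$fit$family, "; imbalance: ", x$strategy,
      " (neg:pos ", x$ratio, ":1)\n", sep = "")
  cat(sprintf("  instances: %d train / %d test; prevalence %.3f\n",
              x$n_train, x$n_test, x$prevalence))
  cat(sprintf("  held-out: AUC %.3f, AUPR %.3f\n",
              x$test_metrics[["AUC"]], x$test_metrics[["AUPR"]]))
  invisible(x)
}

#' @export
summary.synergy_model <- function(object, ...) {
  print(object)
  cat("  held-out metrics:\n")
  m <- unclass(object$test_metrics)
  for (n in names(m)) cat(sprintf("    %-7s %.4f\n", n, m[[n]]))
  if (object$fit$family == "xgboost") {
    imp <- feature_importance_by_block(object$fit)
    cat("  importance by block:\n")
    for (n in names(imp$proportions))
      cat(sprintf("    %-9s %.3f\n", n, imp$proportions[[n]]))
  }
  invisible(object)
}

#' Predict synergy for new instances from a fitted model
#'
#' @param object A `synergy_model`.
#' @param instances Data frame with `drug_a`, `drug_b`, `cell_line`.
#' @param blocks Named list of feature-block matrices covering the instances.
#' @param ... Unused.
#' @return Data frame with `score` and `predicted_label` columns appended.
#' @export
predict.synergy_model <- function(object, instances, blocks, ...) {
  ft <- assemble_features(instances, blocks, object$selection)
  sc <- predict(object$fit, apply_scaler(ft$x, object$scaler))
  data.frame(instances,
             score = sc,
             predicted_label = as.integer(sc > object$threshold),
             row.names = NULL)
}

#' Plot block-level feature importance of a synergy model
#'
#' @param x A `synergy_model` with an xgboost fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.synergy_model <- function(x, ...) {
  imp <- feature_importance_by_block(x$fit)
  graphics::barplot(imp$proportions, las = 2,
                    ylab = "share of total gain importance",
                    main = "Feature importance by block", ...)
  invisible(imp$proportions)
}
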
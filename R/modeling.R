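#' Canonical feature-block order
#'
#' Three drug-pair blocks (summed MACCS keys, summed toxicity terms,
#' combination-pathway scores) followed by five cell-line pathway blocks.
#' @export
BLOCK_ORDER <- c("DD_MACCS", "DD_TOX", "DDP",
                 "EXP", "CNV", "METHY", "MUT", "RNAi")

#' Key identifying one (drug pair, cell line) instance
#'
#' @param drug_a,drug_b,cell_line Character vectors.
#' @return Character `min|max|cell` keys.
#' @export
instance_key <- function(drug_a, drug_b, cell_line) {
  paste(pair_key(drug_a, drug_b), cell_line, sep = "|")
}

#' Assemble a design matrix from feature blocks
#'
#' Selected blocks are concatenated horizontally in canonical order
#' ([BLOCK_ORDER], then any extra blocks in input order). Pair-level blocks
#' are indexed by canonical `a|b` pair key, cell-level blocks by cell line;
#' which applies is inferred from the block's rownames. Column names are
#' prefixed with the block name.
#'
#' @param instances Data frame with `drug_a`, `drug_b`, `cell_line` and
#'   optionally `label`.
#' @param blocks Named list of feature matrices.
#' @param selection Character vector of block names to use (default: all).
#' @return A `feature_table`: list with `x` (design matrix), `y` (labels or
#'   NULL), `block_cols` (block -> column indices), `instances`.
#' @export
assemble_features <- function(instances, blocks, selection = names(blocks)) {
  stopifnot(length(selection) > 0L, all(selection %in% names(blocks)))
  selection <- c(intersect(BLOCK_ORDER, selection),
                 setdiff(selection, BLOCK_ORDER))
  pkeys <- pair_key(instances$drug_a, instances$drug_b)
  parts <- vector("list", length(selection))
  block_cols <- list()
  at <- 0L
  for (s in seq_along(selection)) {
    bl <- blocks[[selection[s]]]
    keys <- if (all(pkeys %in% rownames(bl))) pkeys else instances$cell_line
    miss <- setdiff(unique(keys), rownames(bl))
    if (length(miss))
      stop("block '", selection[s], "' is missing instance '", miss[1L], "'")
    sub <- bl[keys, , drop = FALSE]
    if (ncol(sub) > 0L)
      colnames(sub) <- paste(selection[s], colnames(bl), sep = ".")
    parts[[s]] <- sub
    block_cols[[selection[s]]] <- at + seq_len(ncol(sub))
    at <- at + ncol(sub)
  }
  x <- do.call(cbind, parts)
  rownames(x) <- instance_key(instances$drug_a, instances$drug_b,
                              instances$cell_line)
  structure(list(x = x,
                 y = if ("label" %in% names(instances))
                   as.integer(instances$label) else NULL,
                 block_cols = block_cols,
                 instances = instances),
            class = "feature_table")
}

#' Stratified train/test split with train-fitted standardisation
#'
#' Splits instances into train and test partitions stratified by label, then
#' standardises every column to zero mean and unit variance using statistics
#' estimated on the training partition only (applied to both partitions, so
#' no information flows from test to train). Constant columns are centred
#' and left unscaled.
#'
#' @param x Design matrix.
#' @param y 0/1 label vector.
#' @param test_fraction Fraction of instances held out (default 0.2).
#' @param seed Integer RNG seed.
#' @return List with `train`, `test` (each `list(x, y)`) and `scaler`
#'   (`list(center, scale)`).
#' @export
split_and_scale <- function(x, y, test_fraction = 0.2, seed = 1) {
  stopifnot(nrow(x) == length(y), nrow(x) >= 10L)
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, round(length(ix) * test_fraction))))
  if (length(unique(y[test_idx])) < 2L || length(unique(y[-test_idx])) < 2L)
    stop("a class is absent from one partition; use more data or stratify finer")
  ctr <- colMeans(x[-test_idx, , drop = FALSE])
  scl <- apply(x[-test_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  scale_apply <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = list(x = scale_apply(x[-test_idx, , drop = FALSE]),
                    y = y[-test_idx]),
       test = list(x = scale_apply(x[test_idx, , drop = FALSE]),
                   y = y[test_idx]),
       scaler = list(center = ctr, scale = scl))
}

#' Apply a fitted standardisation scaler
#'
#' @param x Design matrix.
#' @param scaler `list(center, scale)` from [split_and_scale()].
#' @return Standardised matrix.
#' @export
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Rebalance a training set toward a target negative:positive ratio
#'
#' Three strategies for class imbalance (positives = synergistic instances,
#' the minority):
#' \describe{
#'   \item{weights}{no resampling; each class is weighted inversely to its
#'     frequency, so the positive-class weight is the negative:positive
#'     count ratio and the negative-class weight is 1;}
#'   \item{undersample}{randomly drop negative instances until
#'     negatives = `ratio` x positives;}
#'   \item{oversample}{SMOTE: synthesise positive instances by uniform
#'     interpolation between a random positive and one of its `k_smote`
#'     nearest positive neighbours, until negatives = `ratio` x positives.}
#' }
#'
#' @param x Design matrix.
#' @param y 0/1 labels.
#' @param strategy `"weights"`, `"undersample"` or `"oversample"`.
#' @param ratio Target negative:positive count ratio (default 2).
#' @param k_smote Neighbour count for SMOTE synthesis.
#' @param seed Integer RNG seed.
#' @return List with `x`, `y`, `weights` (NULL unless strategy = weights)
#'   and `synthetic` (logical provenance flags; TRUE for SMOTE points).
#' @export
rebalance <- function(x, y, strategy = c("weights", "undersample", "oversample"),
                      ratio = 2, k_smote = 5, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(ratio > 0)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  set.seed(seed)
  if (strategy == "weights") {
    w <- ifelse(y == 1, n_neg / n_pos, 1)
    return(list(x = x, y = y, weights = w,
                synthetic = rep(FALSE, length(y))))
  }
  if (strategy == "undersample") {
    keep_neg <- sample(which(y == 0), min(n_neg, round(ratio * n_pos)))
    idx <- sort(c(which(y == 1), keep_neg))
    return(list(x = x[idx, , drop = FALSE], y = y[idx], weights = NULL,
                synthetic = rep(FALSE, length(idx))))
  }
  # oversample: SMOTE on the positive (minority) class
  target_pos <- round(n_neg / ratio)
  n_new <- max(0L, target_pos - n_pos)
  if (n_new > 0L && n_pos < k_smote + 1L)
    stop("SMOTE needs at least k_smote + 1 = ", k_smote + 1L,
         " minority instances, have ", n_pos)
  if (n_new == 0L)
    return(list(x = x, y = y, weights = NULL,
                synthetic = rep(FALSE, length(y))))
  pos <- x[y == 1, , drop = FALSE]
  dd <- as.matrix(stats::dist(pos))
  diag(dd) <- Inf
  nn <- apply(dd, 1, function(r) order(r)[seq_len(k_smote)])
  base <- sample(nrow(pos), n_new, replace = TRUE)
  mate <- vapply(base, function(i) nn[sample.int(k_smote, 1L), i], 1L)
  gap <- stats::runif(n_new)
  synth <- pos[base, , drop = FALSE] +
    gap * (pos[mate, , drop = FALSE] - pos[base, , drop = FALSE])
  rownames(synth) <- paste0("smote", seq_len(n_new))
  list(x = rbind(x, synth),
       y = c(y, rep(1L, n_new)),
       weights = NULL,
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new)))
}

#' Binary-classification metrics
#'
#' Computes accuracy, precision, recall and F1 at a score threshold
#' (prediction is positive when score > threshold; precision is 0 when
#' nothing is predicted positive), AUC as the Mann-Whitney rank statistic
#' with mid-ranks for ties, and AUPR by step integration of the
#' precision-recall curve over the distinct score thresholds (equivalently,
#' average precision).
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores in \[0, 1\], aligned with `labels`.
#' @param threshold Classification threshold (default 0.5).
#' @return An `evaluation_report`: named numeric vector with elements
#'   `ACC`, `PREC`, `recall`, `F1`, `AUC`, `AUPR`.
#' @export
evaluate <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC/AUPR are undefined for a single-class label vector")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- mean(pred == labels)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  ls <- labels[ord]; ss <- scores[ord]
  grp_end <- which(!duplicated(ss, fromLast = TRUE))  # last index per threshold
  ctp <- cumsum(ls)[grp_end]
  cpp <- grp_end                                      # predicted positives
  precision <- ctp / cpp
  recall <- ctp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(c(ACC = acc, PREC = prec, recall = rec, F1 = f1,
              AUC = auc, AUPR = aupr),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation:", paste(sprintf("%s=%.4f", names(x), unclass(x)),
                           collapse = "  "), "\n")
  invisible(x)
}

#' Fit a synergy classifier on a prepared training matrix
#'
#' Model families: gradient-boosted trees (\pkg{xgboost}; the production
#' configuration), plus logistic regression, lasso-logistic
#' (\pkg{glmnet}), random forest (\pkg{randomForest}) and support-vector
#' machine (\pkg{e1071}) adapters for benchmark comparisons.
#'
#' @param x Standardised design matrix.
#' @param y 0/1 labels.
#' @param family One of `"xgboost"`, `"logistic"`, `"lasso"`,
#'   `"random_forest"`, `"svm"`.
#' @param params For `xgboost`: list with `eta` (learning rate, default
#'   0.1), `max_depth` (default 7) and `nrounds` (default 700). Other
#'   families ignore it.
#' @param weights Optional per-instance weights (class weighting).
#' @param seed Integer RNG seed.
#' @param block_cols Optional block -> column-index map carried along for
#'   importance analysis.
#' @return An object of class `synergy_fit`.
#' @export
fit_synergy <- function(x, y, family = "xgboost",
                        params = list(eta = 0.1, max_depth = 7, nrounds = 700),
                        weights = NULL, seed = 1, block_cols = NULL) {
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  model <- switch(
    family,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y,
                                     weight = if (is.null(weights)) NULL else weights)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta %||% 0.1,
                      max_depth = params$max_depth %||% 7,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds %||% 700, verbose = 0)
    },
    logistic = {
      df <- data.frame(y = y, x, check.names = FALSE)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial(),
                                  weights = weights))
    },
    lasso = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("the lasso family needs the 'glmnet' package")
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5,
                              weights = weights)
      list(cv = cv, lambda = cv$lambda.min)
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("the random_forest family needs the 'randomForest' package")
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = params$nrounds %||% 500)
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("the svm family needs the 'e1071' package")
      e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE,
                 class.weights = if (!is.null(weights))
                   c("0" = 1, "1" = max(weights) / min(weights)) else NULL)
    },
    stop("unknown model family: ", family))
  structure(list(model = model, family = family, params = params,
                 feature_names = colnames(x), block_cols = block_cols,
                 seed = seed, n_train = nrow(x),
                 class_counts = table(factor(y, levels = c(0, 1)))),
            class = "synergy_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict synergy probabilities
#'
#' @param object A `synergy_fit`.
#' @param newdata Standardised design matrix with the training columns.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\].
#' @export
predict.synergy_fit <- function(object, newdata, ...) {
  stopifnot(identical(colnames(newdata), object$feature_names))
  switch(
    object$family,
    xgboost = stats::predict(object$model, xgboost::xgb.DMatrix(newdata)),
    logistic = as.numeric(stats::predict(object$model,
                                         data.frame(newdata, check.names = FALSE),
                                         type = "response")),
    lasso = as.numeric(stats::predict(object$model$cv, newdata,
                                      s = object$model$lambda,
                                      type = "response")),
    random_forest = stats::predict(object$model, newdata,
                                   type = "prob")[, "1"],
    svm = {
      p <- stats::predict(object$model, newdata, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    })
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("Synergy classifier (", x$family, ")\n", sep = "")
  cat("  trained on ", x$n_train, " instances (",
      x$class_counts[["1"]], " positive / ", x$class_counts[["0"]],
      " negative)\n", sep = "")
  cat("  features:", length(x$feature_names))
  if (!is.null(x$block_cols))
    cat(" in", length(x$block_cols), "blocks")
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation with imbalance correction
#'
#' In leak-free mode (default) each fold's training split is rebalanced
#' independently, so no synthetic or resampled point ever derives from a
#' held-out instance. In resample-first mode the full set is rebalanced once
#' and then folded, which lets oversampled copies of an instance appear on
#' both sides of a fold boundary; this optimistic protocol is provided for
#' comparison and its metrics should be read accordingly.
#'
#' @param x Design matrix (standardised).
#' @param y 0/1 labels.
#' @param folds Number of folds (default 5).
#' @param mode `"leak_free"` or `"resample_first"`.
#' @param strategy,ratio,k_smote Passed to [rebalance()].
#' @param family,params Passed to [fit_synergy()].
#' @param seed Integer RNG seed.
#' @param threshold Classification threshold for thresholded metrics.
#' @return A `cv_report`: list with `per_fold` (folds x 6 matrix) and
#'   `mean` (named vector).
#' @export
cross_validate <- function(x, y, folds = 5, mode = c("leak_free", "resample_first"),
                           strategy = "weights", ratio = 2, k_smote = 5,
                           family = "xgboost",
                           params = list(eta = 0.1, max_depth = 7, nrounds = 100),
                           seed = 1, threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(folds >= 2L)
  if (mode == "resample_first") {
    rb <- rebalance(x, y, strategy, ratio, k_smote, seed = seed)
    x <- rb$x; y <- rb$y
    w_all <- rb$weights
  }
  set.seed(seed + 1L)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    fold_id[ix] <- sample(rep(seq_len(folds), length.out = length(ix)))
  }
  per_fold <- matrix(NA_real_, folds, 6,
                     dimnames = list(paste0("fold", seq_len(folds)),
                                     c("ACC", "PREC", "recall", "F1", "AUC", "AUPR")))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(y[!tr] == 1) == 0L) stop("fold ", f, " contains no positives")
    if (mode == "leak_free") {
      rb <- rebalance(x[tr, , drop = FALSE], y[tr], strategy, ratio, k_smote,
                      seed = seed + f)
      fit <- fit_synergy(rb$x, rb$y, family, params, weights = rb$weights,
                         seed = seed + f)
    } else {
      fit <- fit_synergy(x[tr, , drop = FALSE], y[tr], family, params,
                         weights = if (strategy == "weights") w_all[tr] else NULL,
                         seed = seed + f)
    }
    sc <- predict(fit, x[!tr, , drop = FALSE])
    per_fold[f, ] <- unclass(evaluate(y[!tr], sc, threshold))
  }
  structure(list(per_fold = per_fold, mean = colMeans(per_fold),
                 mode = mode, strategy = strategy),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation (", nrow(x$per_fold), " folds, ", x$mode, ", ",
      x$strategy, ")\n", sep = "")
  cat("  mean:", paste(sprintf("%s=%.4f", names(x$mean), x$mean),
                       collapse = "  "), "\n")
  invisible(x)
}

#' Exhaustive hyperparameter grid search by cross-validated AUPR
#'
#' Every grid point is scored by mean cross-validated AUPR on the training
#' partition; ties keep the first point in grid order. The production
#' default grid spans learning rates \{0.05, 0.1, 0.3\}, depths \{5, 7, 9\}
#' and \{300, 500, 700\} boosting rounds.
#'
#' @param x,y Training design matrix and labels.
#' @param grid Data frame with columns `eta`, `max_depth`, `nrounds`.
#' @param ... Passed to [cross_validate()].
#' @return List with `best` (named list of the winning parameters) and
#'   `results` (grid with an `AUPR` column).
#' @export
grid_search <- function(x, y,
                        grid = expand.grid(eta = c(0.05, 0.1, 0.3),
                                           max_depth = c(5, 7, 9),
                                           nrounds = c(300, 500, 700)),
                        ...) {
  stopifnot(nrow(grid) >= 1L)
  aupr <- vapply(seq_len(nrow(grid)), function(i) {
    cv <- cross_validate(x, y,
                         params = list(eta = grid$eta[i],
                                       max_depth = grid$max_depth[i],
                                       nrounds = grid$nrounds[i]),
                         ...)
    cv$mean[["AUPR"]]
  }, 0)
  best_i <- which.max(aupr)  # which.max keeps the first maximum
  res <- cbind(grid, AUPR = aupr)
  list(best = as.list(grid[best_i, , drop = FALSE]), results = res)
}

#' Evaluate every non-empty subset of the feature blocks
#'
#' All `2^B - 1` block subsets are trained and evaluated with an identical
#' configuration (same split seed, imbalance strategy and model
#' hyperparameters). Subsets are ranked separately on recall, F1 and AUPR
#' (rank 1 = best, min-rank for ties); the table is ordered by the average
#' of the three ranks, ties broken by AUPR and then by subset bitmask.
#'
#' @param instances Labelled instances (`drug_a`, `drug_b`, `cell_line`,
#'   `label`).
#' @param blocks Named list of feature-block matrices.
#' @param strategy,ratio,k_smote Imbalance handling (see [rebalance()]).
#' @param family,params Model configuration (see [fit_synergy()]).
#' @param test_fraction,seed Split configuration (see [split_and_scale()]).
#' @param threshold Classification threshold.
#' @return Data frame with one row per subset: `subset` (comma-joined block
#'   names), `bitmask`, the six metrics, the three metric ranks and
#'   `avg_rank`; ordered best-first.
#' @export
feature_set_search <- function(instances, blocks, strategy = "weights",
                               ratio = 2, k_smote = 5, family = "xgboost",
                               params = list(eta = 0.1, max_depth = 7, nrounds = 100),
                               test_fraction = 0.2, seed = 1, threshold = 0.5) {
  bnames <- c(intersect(BLOCK_ORDER, names(blocks)),
              setdiff(names(blocks), BLOCK_ORDER))
  B <- length(bnames)
  masks <- seq_len(2^B - 1L)
  rows <- vector("list", length(masks))
  for (mask in masks) {
    sel <- bnames[bitwAnd(mask, 2^(seq_len(B) - 1L)) > 0L]
    ft <- assemble_features(instances, blocks, sel)
    sp <- split_and_scale(ft$x, ft$y, test_fraction, seed)
    rb <- rebalance(sp$train$x, sp$train$y, strategy, ratio, k_smote, seed)
    fit <- fit_synergy(rb$x, rb$y, family, params, weights = rb$weights,
                       seed = seed)
    ev <- evaluate(sp$test$y, predict(fit, sp$test$x), threshold)
    rows[[mask]] <- data.frame(subset = paste(sel, collapse = ","),
                               bitmask = mask, t(unclass(ev)))
  }
  out <- do.call(rbind, rows)
  out$rank_recall <- rank(-out$recall, ties.method = "min")
  out$rank_F1 <- rank(-out$F1, ties.method = "min")
  out$rank_AUPR <- rank(-out$AUPR, ties.method = "min")
  out$avg_rank <- (out$rank_recall + out$rank_F1 + out$rank_AUPR) / 3
  out <- out[order(out$avg_rank, -out$AUPR, out$bitmask), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Block-level importance of a fitted tree ensemble
#'
#' Per-feature gain importances of the boosted-tree model are summed within
#' each feature block and normalised to proportions (summing to 1); features
#' never used by the ensemble contribute 0. Also returns the per-block
#' descending feature ranking used for top-k selection.
#'
#' @param fit A `synergy_fit` with family `"xgboost"` and a `block_cols` map.
#' @return List with `proportions` (named numeric, sums to 1) and `ranking`
#'   (block -> character vector of feature names, most important first).
#' @export
feature_importance_by_block <- function(fit) {
  stopifnot(inherits(fit, "synergy_fit"))
  if (fit$family != "xgboost")
    stop("gain importances are only defined for tree-ensemble fits")
  if (is.null(fit$block_cols))
    stop("fit carries no block -> column map")
  imp <- xgboost::xgb.importance(model = fit$model)
  gain <- stats::setNames(rep(0, length(fit$feature_names)), fit$feature_names)
  gain[imp$Feature] <- imp$Gain
  per_block <- vapply(fit$block_cols, function(ix)
    sum(gain[fit$feature_names[ix]]), 0)
  total <- sum(per_block)
  proportions <- if (total > 0) per_block / total else
    rep(1 / length(per_block), length(per_block))
  names(proportions) <- names(fit$block_cols)
  ranking <- lapply(fit$block_cols, function(ix) {
    f <- fit$feature_names[ix]
    f[order(-gain[f])]
  })
  list(proportions = proportions, ranking = ranking)
}

#' Refit on the top-k features of each block
#'
#' For each k, the k most important features of every selected block are
#' kept, the model is refit with the shared configuration and all six
#' metrics are reported, tracing how quickly a handful of features per
#' block recovers full-model performance. k larger than a block is capped
#' at the block width with a warning.
#'
#' @param instances Labelled instances.
#' @param blocks Named list of feature-block matrices.
#' @param ranking Block -> feature ranking from
#'   [feature_importance_by_block()] (feature names carry the
#'   `block.column` prefix).
#' @param ks Integer vector of k values (default 1:5 and 10).
#' @param ... Configuration passed as in [feature_set_search()].
#' @return Data frame with one row per k and the six metrics.
#' @export
top_k_refit <- function(instances, blocks, ranking, ks = c(1:5, 10),
                        strategy = "weights", ratio = 2, k_smote = 5,
                        family = "xgboost",
                        params = list(eta = 0.1, max_depth = 7, nrounds = 100),
                        test_fraction = 0.2, seed = 1, threshold = 0.5) {
  sel <- names(ranking)
  ft <- assemble_features(instances, blocks, sel)
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    keep <- unlist(lapply(ranking, function(f) {
      if (k > length(f))
        warning("k = ", k, " exceeds a block width; capped at ", length(f))
      f[seq_len(min(k, length(f)))]
    }), use.names = FALSE)
    xk <- ft$x[, keep, drop = FALSE]
    sp <- split_and_scale(xk, ft$y, test_fraction, seed)
    rb <- rebalance(sp$train$x, sp$train$y, strategy, ratio, k_smote, seed)
    fit <- fit_synergy(rb$x, rb$y, family, params, weights = rb$weights,
                       seed = seed)
    ev <- evaluate(sp$test$y, predict(fit, sp$test$x), threshold)
    rows[[i]] <- data.frame(k = k, n_features = length(keep), t(unclass(ev)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score the unlabelled remainder of the (pair x cell line) grid
#'
#' Enumerates every unordered drug pair crossed with every cell line, drops
#' the labelled instances, assembles features with the model's blocks,
#' applies the training scaler and predicts.
#'
#' @param fit A `synergy_fit`.
#' @param scaler Scaler from the training split.
#' @param blocks Named list of feature-block matrices.
#' @param selection Block selection used at training time.
#' @param drug_ids Character vector of drugs.
#' @param cell_lines Character vector of cell lines.
#' @param labeled_keys Character vector of [instance_key()] values already
#'   labelled.
#' @param threshold Classification threshold.
#' @return Data frame: `drug_a`, `drug_b`, `cell_line`, `score`,
#'   `predicted_label`.
#' @export
predict_unlabeled <- function(fit, scaler, blocks, selection, drug_ids,
                              cell_lines, labeled_keys, threshold = 0.5) {
  pairs <- all_drug_pairs(drug_ids)
  grid <- data.frame(drug_a = rep(pairs$drug_a, each = length(cell_lines)),
                     drug_b = rep(pairs$drug_b, each = length(cell_lines)),
                     cell_line = rep(cell_lines, nrow(pairs)),
                     stringsAsFactors = FALSE)
  keys <- instance_key(grid$drug_a, grid$drug_b, grid$cell_line)
  grid <- grid[!keys %in% labeled_keys, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      cell_line = character(0), score = numeric(0),
                      predicted_label = integer(0)))
  ft <- assemble_features(grid, blocks, selection)
  sc <- predict(fit, apply_scaler(ft$x, scaler))
  data.frame(grid, score = sc, predicted_label = as.integer(sc > threshold),
             row.names = NULL)
}
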
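# shared toy blocks: 6 drugs x 2 cells, pair blocks + cell blocks
toy_blocks <- function(n_drugs = 6, n_cells = 2, seed = 4) {
  set.seed(seed)
  drugs <- paste0("d", seq_len(n_drugs))
  cells <- paste0("c", seq_len(n_cells))
  pairs <- all_drug_pairs(drugs)
  pk <- pair_key(pairs$drug_a, pairs$drug_b)
  mk <- function(keys, w, prefix) {
    m <- matrix(rnorm(length(keys) * w), length(keys), w,
                dimnames = list(keys, paste0(prefix, seq_len(w))))
    m
  }
  blocks <- list(DDP = mk(pk, 3, "p"), EXP = mk(cells, 4, "e"),
                 MUT = mk(cells, 2, "m"))
  inst <- data.frame(drug_a = rep(pairs$drug_a, each = n_cells),
                     drug_b = rep(pairs$drug_b, each = n_cells),
                     cell_line = rep(cells, nrow(pairs)),
                     stringsAsFactors = FALSE)
  list(blocks = blocks, instances = inst, pairs = pairs, cells = cells)
}

test_that("feature assembly concatenates blocks in canonical order", {
  tb <- toy_blocks()
  inst <- tb$instances
  inst$label <- rbinom(nrow(inst), 1, 0.3)
  ft <- assemble_features(inst, tb$blocks)
  expect_equal(ncol(ft$x), 3 + 4 + 2)
  expect_identical(names(ft$block_cols), c("DDP", "EXP", "MUT"))
  expect_identical(colnames(ft$x)[1:3], paste0("DDP.p", 1:3))
  one <- assemble_features(inst, tb$blocks, "DDP")
  expect_equal(ncol(one$x), 3)
  # pair rows come from the pair block, cell rows from the cell block
  expect_equal(unname(ft$x[1, 4:7]),
               unname(tb$blocks$EXP[inst$cell_line[1], ]))
  # missing instance is named
  bad <- inst; bad$cell_line[1] <- "c99"
  expect_error(assemble_features(bad, tb$blocks), "c99")
})

test_that("split is stratified, deterministic, and scaling is train-fitted", {
  set.seed(10)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[, 5] <- 7                     # constant column
  y <- rep(c(0L, 1L), c(75, 25))
  sp <- split_and_scale(x, y, 0.2, seed = 99)
  expect_equal(nrow(sp$test$x), 20)
  expect_equal(sum(sp$test$y), 5)   # stratified 20% of 25 positives
  expect_equal(unname(colMeans(sp$train$x[, 1:4])), rep(0, 4),
               tolerance = 1e-9)
  expect_equal(unname(apply(sp$train$x[, 1:4], 2, sd)), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(unname(sp$train$x[, 5]), rep(0, 80))  # constant col centred
  sp2 <- split_and_scale(x, y, 0.2, seed = 99)
  expect_identical(sp, sp2)
  # test partition uses train statistics, not its own
  expect_false(isTRUE(all.equal(unname(colMeans(sp$test$x[, 1:4])),
                                rep(0, 4), tolerance = 1e-9)))
})

test_that("rebalancing reaches the requested class ratio", {
  set.seed(5)
  mk <- function(n) matrix(rnorm(n * 3), n, 3,
                           dimnames = list(NULL, c("a", "b", "c")))
  # undersample: 100 neg / 30 pos at ratio 2 -> 60 neg retained
  x <- mk(130); y <- rep(c(0L, 1L), c(100, 30))
  u <- rebalance(x, y, "undersample", ratio = 2, seed = 1)
  expect_equal(sum(u$y == 0), 60)
  expect_equal(sum(u$y == 1), 30)
  # oversample: 40 neg / 10 pos at ratio 2 -> 20 pos after synthesis
  x2 <- mk(50); y2 <- rep(c(0L, 1L), c(40, 10))
  o <- rebalance(x2, y2, "oversample", ratio = 2, k_smote = 3, seed = 1)
  expect_equal(sum(o$y == 1), 20)
  expect_equal(sum(o$y == 0), 40)
  expect_equal(sum(o$synthetic), 10)
  # weights: positive-class weight is the negative:positive count ratio
  yw <- rep(c(0L, 1L), c(114075, 14371))
  w <- rebalance(matrix(0, length(yw), 1), yw, "weights", seed = 1)
  expect_equal(unique(w$weights[yw == 1]) / unique(w$weights[yw == 0]),
               114075 / 14371, tolerance = 1e-9)
  expect_error(rebalance(mk(8), rep(c(0L, 1L), c(5, 3)), "oversample",
                         ratio = 1, k_smote = 5),
               "k_smote")
})

test_that("SMOTE points interpolate between minority neighbours", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(16, 10, 1), 8, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0L, 1L), c(30, 8))
  o <- rebalance(x, y, "oversample", ratio = 2, k_smote = 3, seed = 2)
  synth <- o$x[o$synthetic, , drop = FALSE]
  pos <- x[y == 1, ]
  # synthetic points stay inside the minority bounding box
  expect_true(all(synth[, 1] >= min(pos[, 1]) & synth[, 1] <= max(pos[, 1])))
  expect_true(all(synth[, 2] >= min(pos[, 2]) & synth[, 2] <= max(pos[, 2])))
  expect_true(all(o$y[o$synthetic] == 1L))
})

test_that("resampling never draws on held-out instances in leak-free folds", {
  # train minority lives near 0, a would-be test positive lives at 100; no
  # synthetic point may approach it
  set.seed(12)
  x_tr <- matrix(c(rnorm(40, 0, 1), rnorm(8, 1, 0.5)), ncol = 1)
  y_tr <- rep(c(0L, 1L), c(40, 8))
  o <- rebalance(x_tr, y_tr, "oversample", ratio = 2, k_smote = 3, seed = 3)
  expect_true(all(abs(o$x[o$synthetic, 1]) < 50))
})

test_that("metrics match hand-computed confusion arithmetic", {
  ev <- evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unclass(ev),
               c(ACC = 1, PREC = 1, recall = 1, F1 = 1, AUC = 1, AUPR = 1))
  ev2 <- evaluate(c(1, 0), c(0.4, 0.6))
  expect_equal(ev2[["recall"]], 0)
  expect_equal(ev2[["F1"]], 0)
  expect_equal(ev2[["AUC"]], 0)
  expect_error(evaluate(c(1, 1), c(0.2, 0.3)), "single-class")
  # random scores at prevalence 0.1: AUPR concentrates near the prevalence
  set.seed(14)
  n <- 40000
  lab <- rbinom(n, 1, 0.1)
  ev3 <- evaluate(lab, runif(n))
  expect_equal(ev3[["AUPR"]], 0.1, tolerance = 0.02)
  expect_equal(ev3[["AUC"]], 0.5, tolerance = 0.02)
})

test_that("cross-validation folds are stratified and means aggregate folds", {
  td <- toy_model_data(n = 300, prevalence = 0.3, signal = 2, seed = 6)
  cv <- cross_validate(td$x, td$y, folds = 5, strategy = "weights",
                       params = list(eta = 0.2, max_depth = 3, nrounds = 20),
                       seed = 7)
  expect_equal(dim(cv$per_fold), c(5L, 6L))
  expect_equal(cv$mean, colMeans(cv$per_fold))
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 1))
})

test_that("grid search picks the dominant point deterministically", {
  td <- toy_model_data(n = 250, prevalence = 0.3, signal = 3, seed = 8)
  single <- grid_search(td$x, td$y,
                        grid = data.frame(eta = 0.2, max_depth = 3,
                                          nrounds = 25),
                        folds = 3, seed = 9)
  expect_equal(single$best$nrounds, 25)
  g <- data.frame(eta = c(0.2, 0.2), max_depth = c(3, 3), nrounds = c(1, 60))
  gs1 <- grid_search(td$x, td$y, grid = g, folds = 3, seed = 9)
  expect_equal(gs1$best$nrounds, 60)   # the trained model dominates 1 round
  gs2 <- grid_search(td$x, td$y, grid = g, folds = 3, seed = 9)
  expect_identical(gs1$results, gs2$results)
})

test_that("feature-set search enumerates every non-empty subset", {
  tb <- toy_blocks(n_drugs = 8, n_cells = 4, seed = 15)
  inst <- tb$instances
  set.seed(16)
  # label is a pure function of the pair, and the DDP block carries it as a
  # perfect feature, so any subset containing DDP dominates recall, F1 and
  # AUPR simultaneously
  pairs_pos <- sample(unique(pair_key(inst$drug_a, inst$drug_b)), 9)
  pk <- pair_key(inst$drug_a, inst$drug_b)
  inst$label <- as.integer(pk %in% pairs_pos)
  tb$blocks$DDP[, 1] <- as.numeric(rownames(tb$blocks$DDP) %in% pairs_pos)
  res <- feature_set_search(inst, tb$blocks,
                            params = list(eta = 0.3, max_depth = 2,
                                          nrounds = 40),
                            test_fraction = 0.3, seed = 17)
  expect_equal(nrow(res), 7)   # 2^3 - 1
  expect_equal(res$avg_rank[1], 1)
  expect_match(res$subset[1], "DDP")
})

test_that("block importance is a normalised decomposition of gain", {
  td <- toy_model_data(n = 300, prevalence = 0.3, signal = 4, seed = 18)
  block_cols <- list(SIG = 1:2, NOISE = 3:4)
  fit <- fit_synergy(td$x, td$y, params = list(eta = 0.2, max_depth = 3,
                                               nrounds = 40),
                     block_cols = block_cols, seed = 19)
  imp <- feature_importance_by_block(fit)
  expect_equal(sum(imp$proportions), 1, tolerance = 1e-9)
  expect_gt(imp$proportions[["SIG"]], imp$proportions[["NOISE"]])
  expect_identical(sort(unlist(imp$ranking, use.names = FALSE)),
                   sort(colnames(td$x)))
  fit1 <- fit_synergy(td$x[, 1:2], td$y,
                      params = list(eta = 0.2, max_depth = 3, nrounds = 20),
                      block_cols = list(SIG = 1:2), seed = 19)
  expect_equal(feature_importance_by_block(fit1)$proportions[["SIG"]], 1)
  lg <- fit_synergy(td$x, td$y, family = "logistic")
  expect_error(feature_importance_by_block(lg), "tree-ensemble")
})

test_that("top-k refits trace metrics over k and cap k at the block width", {
  tb <- toy_blocks(n_drugs = 8, n_cells = 4, seed = 20)
  inst <- tb$instances
  set.seed(21)
  inst$label <- rbinom(nrow(inst), 1, 0.35)
  ranking <- list(DDP = paste0("DDP.p", 1:3), EXP = paste0("EXP.e", 1:4))
  out <- suppressWarnings(
    top_k_refit(inst, tb$blocks, ranking, ks = c(1, 2, 10),
                params = list(eta = 0.3, max_depth = 2, nrounds = 15),
                test_fraction = 0.3, seed = 22))
  expect_equal(out$k, c(1, 2, 10))
  expect_equal(out$n_features, c(2L, 4L, 7L))  # k=10 capped at 3+4
  expect_warning(
    top_k_refit(inst, tb$blocks, ranking["EXP"], ks = 10,
                params = list(eta = 0.3, max_depth = 2, nrounds = 5),
                test_fraction = 0.3, seed = 22),
    "capped")
})

test_that("unlabelled prediction scores exactly the grid complement", {
  tb <- toy_blocks(n_drugs = 3, n_cells = 2, seed = 23)
  inst <- tb$instances           # 3 pairs x 2 cells = 6
  set.seed(24)
  inst$label <- c(0L, 1L, 0L, 1L, 0L, 1L)
  labeled <- inst[1:4, ]
  ft <- assemble_features(labeled, tb$blocks)
  sp <- list(center = colMeans(ft$x), scale = apply(ft$x, 2, sd))
  sp$scale[sp$scale == 0] <- 1
  fit <- fit_synergy(apply_scaler(ft$x, sp), labeled$label,
                     params = list(eta = 0.3, max_depth = 2, nrounds = 5),
                     seed = 25)
  keys <- instance_key(labeled$drug_a, labeled$drug_b, labeled$cell_line)
  pred <- predict_unlabeled(fit, sp, tb$blocks, names(tb$blocks),
                            paste0("d", 1:3), paste0("c", 1:2), keys)
  expect_equal(nrow(pred), 2)   # 6 - 4
  pred_keys <- instance_key(pred$drug_a, pred$drug_b, pred$cell_line)
  all_keys <- instance_key(inst$drug_a, inst$drug_b, inst$cell_line)
  expect_length(intersect(pred_keys, keys), 0)
  expect_setequal(c(pred_keys, keys), all_keys)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("the top-level model wrapper fits, predicts and summarises", {
  tb <- toy_blocks(n_drugs = 10, n_cells = 4, seed = 26)
  inst <- tb$instances
  set.seed(27)
  # label depends on the DDP block so the model has something to learn
  pk <- pair_key(inst$drug_a, inst$drug_b)
  lin <- tb$blocks$DDP[pk, 1] + 0.5 * tb$blocks$DDP[pk, 2]
  inst$label <- as.integer(lin + rnorm(nrow(inst), 0, 0.3) >
                             quantile(lin, 0.7))
  m <- synergy_model(inst, tb$blocks,
                     params = list(eta = 0.2, max_depth = 3, nrounds = 50),
                     seed = 28)
  expect_s3_class(m, "synergy_model")
  expect_true(m$test_metrics[["AUC"]] > 0.6)
  expect_output(print(m), "Pathway-bridged")
  expect_output(summary(m), "importance by block")
  pred <- predict(m, inst[1:5, c("drug_a", "drug_b", "cell_line")], tb$blocks)
  expect_equal(nrow(pred), 5)
  expect_true(all(pred$predicted_label %in% 0:1))
})

test_that("alternative classifier families run behind the same interface", {
  td <- toy_model_data(n = 150, prevalence = 0.3, signal = 3, seed = 29)
  for (fam in c("logistic", "random_forest")) {
    fit <- fit_synergy(td$x, td$y, family = fam)
    sc <- predict(fit, td$x)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(evaluate(td$y, sc)[["AUC"]], 0.7)
  }
})
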
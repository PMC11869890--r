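# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately use naive loops and set arithmetic, never the
# package's vectorised code paths.

# ---- pathway-bridge oracle: indicator, Jaccard, refinement and pair scores
# computed entry by entry from the raw sets -------------------------------
naive_bridge <- function(targets, sets) {
  m <- length(targets); n <- length(sets)
  D <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    D[i, j] <- as.numeric(length(intersect(targets[[i]], sets[[j]])) > 0)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    P[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  Dref <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    for (k in seq_len(n)) Dref[i, j] <- Dref[i, j] + D[i, k] * P[k, j]
  A <- array(0, c(m, m, n))
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(n))
    A[i, j, k] <- (D[i, k] * Dref[j, k] + D[j, k] * Dref[i, k]) / 2
  list(D = D, P = P, Dref = Dref, A = A)
}

# random drug-table + gene-set fixture
rand_fixture <- function(m, n, n_genes = 40) {
  genes <- sprintf("x%02d", seq_len(n_genes))
  sets <- lapply(seq_len(n), function(j) sample(genes, sample(3:8, 1)))
  names(sets) <- sprintf("P%02d", seq_len(n))
  targets <- lapply(seq_len(m), function(i) sample(genes, sample(2:6, 1)))
  drugs <- data.frame(drug_id = sprintf("D%02d", seq_len(m)),
                      smiles = NA_character_,
                      target_genes = I(targets),
                      toxicity_terms = I(replicate(m, character(0),
                                                   simplify = FALSE)),
                      stringsAsFactors = FALSE)
  list(drugs = drugs, genesets = gene_set_collection(sets),
       targets = targets, sets = sets)
}

# ---- classification-metric oracle: confusion arithmetic and curve areas
# recomputed from scratch, one threshold at a time ------------------------
naive_metrics <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- tp / sum(labels)
  # AUPR: step integration over every distinct threshold
  cuts <- sort(unique(scores), decreasing = TRUE)
  last_r <- 0; aupr <- 0
  for (s in cuts) {
    p <- scores >= s
    tpc <- sum(p & labels)
    pr <- tpc / sum(p)
    rc <- tpc / sum(labels)
    aupr <- aupr + (rc - last_r) * pr
    last_r <- rc
  }
  c(ACC = mean(pred == labels), PREC = prec, recall = rec,
    F1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    AUPR = aupr)
}

# frozen single-sample gene-set variation fixture: 12 genes x 4 cell lines,
# scored once with an independent reference implementation (Gaussian kernel,
# tau = 1, max-deviation statistic)
gsva_ref_fixture <- function() {
  m <- matrix(c(
    5.6094, 2.9200, 6.5009, 6.8811,
    1.0979, 2.3956, 5.2557, 4.3675,
    4.9664, 3.2939, 6.7588, 6.5556,
    5.1321, 7.2545, 5.9350, 3.2814,
    5.7375, 3.0822, 6.7569, 4.9001,
    4.6303, 3.6381, 7.4451, 4.6909,
    4.1433, 4.2957, 6.0646, 5.7309,
    5.8255, 5.8616, 9.2833, 4.1872,
    3.9755, 3.3725, 6.2320, 7.2579,
    4.7721, 3.3197, 3.3510, 6.3012,
    6.4865, 6.0863, 3.6690, 5.4643,
    5.2334, 5.4374, 6.7429, 5.4472), nrow = 12, byrow = TRUE,
    dimnames = list(paste0("g", 1:12), paste0("c", 1:4)))
  ref <- matrix(c(
    -0.7142857142857143, -0.375, -0.5, -0.3846153846153846,
    0.3571428571428571, -0.2976190476190476,
    0.6571428571428571, -0.3571428571428571),
    nrow = 2, byrow = TRUE, dimnames = list(c("P1", "P2"), paste0("c", 1:4)))
  list(m = m,
       genesets = gene_set_collection(list(P1 = paste0("g", 1:4),
                                           P2 = paste0("g", 5:9))),
       ref = ref)
}

# tiny labelled modelling fixture with a controllable signal column
toy_model_data <- function(n = 200, prevalence = 0.25, signal = 3, seed = 1) {
  set.seed(seed)
  y <- as.integer(runif(n) < prevalence)
  x <- cbind(s1 = y * signal + rnorm(n),
             s2 = y * signal / 2 + rnorm(n),
             noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(x) <- paste0("i", seq_len(n))
  list(x = x, y = y)
}
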
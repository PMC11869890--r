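make_drugs <- function(targets) {
  data.frame(drug_id = names(targets), smiles = NA_character_,
             target_genes = I(unname(targets)),
             toxicity_terms = I(replicate(length(targets), character(0),
                                          simplify = FALSE)),
             stringsAsFactors = FALSE)
}

test_that("density screening applies inclusive boundaries in order", {
  genes <- sprintf("g%02d", 1:60)
  drugs <- make_drugs(list(d_small = genes[1:9],       # 9 targets: dropped
                           d_ok = genes[1:10],         # exactly 10: kept
                           d_big = genes[1:20]))
  gsc <- gene_set_collection(list(
    P_small = genes[1:9],          # 9 genes: dropped
    P_cover = genes[1:10],         # 10 genes, hit by both retained drugs
    P_half = genes[11:21]))        # hit only by d_big: 1/2 of drugs = kept
  out <- filter_drugs_and_pathways(drugs, gsc)
  expect_identical(out$drugs$drug_id, c("d_ok", "d_big"))
  expect_identical(out$genesets$pathway_ids, c("P_cover", "P_half"))
})

test_that("the drug-coverage fraction uses the retained drugs as denominator", {
  # 88 drugs, one below the target threshold -> 87 retained; a pathway hit
  # by 43 of them misses the half bound (43 < 43.5), one hit by 44 makes it
  genes <- sprintf("g%03d", 1:400)
  core <- genes[1:10]            # hit by every drug so one pathway survives
  probe43 <- "g020"; probe44 <- "g021"
  targets <- lapply(1:88, function(i) {
    t <- c(core, genes[100 + ((10 * i):(10 * i + 5)) %% 250])
    if (i <= 43) t <- c(t, probe43)
    if (i <= 44) t <- c(t, probe44)
    unique(t)
  })
  names(targets) <- sprintf("d%02d", 1:88)
  targets$d88 <- genes[1:9]      # dropped by the target screen
  drugs <- make_drugs(targets)
  # filler genes sit outside every drug's target range (g101..g350)
  gsc <- gene_set_collection(list(
    P_core = core,
    P_43 = c(probe43, genes[360:368]),
    P_44 = c(probe44, genes[370:378])))
  out <- filter_drugs_and_pathways(drugs, gsc)
  expect_equal(nrow(out$drugs), 87)
  expect_false("P_43" %in% out$genesets$pathway_ids)
  expect_true("P_44" %in% out$genesets$pathway_ids)
})

test_that("screening errors when everything is filtered away", {
  drugs <- make_drugs(list(d1 = c("g1", "g2")))
  gsc <- gene_set_collection(list(P1 = sprintf("g%02d", 1:12)))
  expect_error(filter_drugs_and_pathways(drugs, gsc), "all drugs removed")
})

test_that("indicator matrix flags non-empty target/pathway intersections", {
  drugs <- make_drugs(list(d1 = "g1", d2 = "g9"))
  gsc <- gene_set_collection(list(P1 = c("g1", "g2"), P2 = c("g9")))
  D <- build_drug_pathway_matrix(drugs, gsc)
  expect_equal(D, matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(c("d1", "d2"), c("P1", "P2"))))
})

test_that("pathway similarity is set-level Jaccard with unit diagonal", {
  gsc <- gene_set_collection(list(A = c("g1", "g2", "g3"),
                                  B = c("g2", "g3", "g4"),
                                  C = c("g9", "g8")))
  P <- build_pathway_similarity(gsc)
  expect_equal(P["A", "B"], 0.5)   # 2 shared / 4 union
  expect_equal(P["A", "C"], 0)
  expect_equal(diag(P), c(A = 1, B = 1, C = 1))
  expect_identical(P, t(P))
})

test_that("refinement is the indicator-similarity product", {
  D <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("d1", "d2"), c("A", "B")))
  P <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(refine_drug_pathway(D, P),
               matrix(c(1, 0.5, 0.5, 1), 2, 2,
                      dimnames = dimnames(D)))
  expect_equal(refine_drug_pathway(D, diag(2)), D, ignore_attr = TRUE)
  D0 <- rbind(D, d3 = c(0, 0))
  expect_equal(unname(refine_drug_pathway(D0, P)["d3", ]), c(0, 0))
  expect_error(refine_drug_pathway(D, diag(3)), "conformable")
})

test_that("combination scores follow the symmetrised product formula", {
  D <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("d1", "d2"), c("A", "B")))
  P <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  A <- build_combination_pathway_features(D, refine_drug_pathway(D, P),
                                          data.frame(a = "d1", b = "d2"))
  expect_equal(A["d1|d2", "A"], 0.25)  # (1*0.5 + 0*1)/2
  expect_equal(A["d1|d2", "B"], 0.25)
  expect_error(build_combination_pathway_features(
    D, refine_drug_pathway(D, P), data.frame(a = "d1", b = "dX")),
    "unknown drug")
})

test_that("vectorised bridge equals the brute-force oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:10) {
    fx <- rand_fixture(sample(3:6, 1), sample(3:5, 1))
    oracle <- naive_bridge(fx$targets, fx$sets)
    D <- build_drug_pathway_matrix(fx$drugs, fx$genesets)
    P <- build_pathway_similarity(fx$genesets)
    Dref <- refine_drug_pathway(D, P)
    expect_equal(unname(D), oracle$D, tolerance = 1e-12)
    expect_equal(unname(P), oracle$P, tolerance = 1e-12)
    expect_equal(unname(Dref), oracle$Dref, tolerance = 1e-12)
    pairs <- all_drug_pairs(fx$drugs$drug_id)
    A <- build_combination_pathway_features(D, Dref, pairs)
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$drug_a[r], fx$drugs$drug_id)
      j <- match(pairs$drug_b[r], fx$drugs$drug_id)
      expect_equal(unname(A[r, ]), oracle$A[i, j, ], tolerance = 1e-12)
    }
    # invariants: pair symmetry, zero where neither drug acts, refinement
    # dominates the indicator, non-negativity
    A_swap <- build_combination_pathway_features(D, Dref, pairs[, c(2, 1)])
    expect_equal(A, A_swap)
    expect_true(all(Dref - D >= -1e-12))
    expect_true(all(A >= 0))
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$drug_a[r], fx$drugs$drug_id)
      j <- match(pairs$drug_b[r], fx$drugs$drug_id)
      both_zero <- D[i, ] == 0 & D[j, ] == 0
      expect_true(all(A[r, both_zero] == 0))
    }
  }
})

test_that("screening results are invariant to input row and file order", {
  set.seed(5)
  fx <- rand_fixture(8, 6, n_genes = 30)
  # loosen thresholds so something survives on the small fixture
  args <- list(min_targets = 2, min_genes = 3, min_drug_fraction = 0.5)
  out1 <- do.call(filter_drugs_and_pathways, c(list(fx$drugs, fx$genesets), args))
  perm_d <- sample(nrow(fx$drugs))
  perm_p <- sample(length(fx$genesets$sets))
  out2 <- do.call(filter_drugs_and_pathways,
                  c(list(fx$drugs[perm_d, ],
                         gene_set_collection(fx$genesets$sets[perm_p])), args))
  expect_setequal(out1$drugs$drug_id, out2$drugs$drug_id)
  expect_setequal(out1$genesets$pathway_ids, out2$genesets$pathway_ids)
})
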
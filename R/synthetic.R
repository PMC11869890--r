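#' Configuration for the synthetic study generator
#'
#' Defaults give a desk-scale study that runs the full pipeline in minutes:
#' 500 genes, 20 drugs (so 190 unordered pairs), 30 pathways of 10-50
#' genes, 12 cell lines and 9 dose points per (pair, cell line), emulating
#' a 3x3 concentration grid. Every drug draws at least `targets_per_drug[1]`
#' >= 10 targets so the density screen is satisfiable by construction. The
#' planted synergy signal has strength `alpha` (percent-growth points per
#' standard deviation of the pathway-bridge signal), instance-level noise
#' `sigma` and dose-level noise `sigma_dose`; `label_quantile` positions the
#' labelling threshold so roughly 10\% of instances are synergistic.
#'
#' @param n_genes,n_drugs,n_pathways,n_cell_lines Universe dimensions.
#' @param pathway_size Integer range of genes per pathway.
#' @param targets_per_drug Integer range of target genes per drug.
#' @param n_tox_terms Size of the toxicity vocabulary.
#' @param dose_points Dose points per (pair, cell line).
#' @param alpha Planted signal strength; 0 severs all feature-label
#'   dependence.
#' @param sigma Instance-level synergy noise sd.
#' @param sigma_dose Dose-level measurement noise sd.
#' @param na_rate Missing-value rate for METHY/RNAi matrices.
#' @param label_quantile Quantile of planted synergy used as the default
#'   labelling threshold.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_drugs = 20, n_pathways = 30,
                       n_cell_lines = 12, pathway_size = c(10, 50),
                       targets_per_drug = c(10, 25), n_tox_terms = 40,
                       dose_points = 9, alpha = 10, sigma = 1,
                       sigma_dose = 3, na_rate = 0.05,
                       label_quantile = 0.9, seed = 1) {
  cfg <- list(n_genes = n_genes, n_drugs = n_drugs, n_pathways = n_pathways,
              n_cell_lines = n_cell_lines, pathway_size = pathway_size,
              targets_per_drug = targets_per_drug, n_tox_terms = n_tox_terms,
              dose_points = dose_points, alpha = alpha, sigma = sigma,
              sigma_dose = sigma_dose, na_rate = na_rate,
              label_quantile = label_quantile, seed = seed)
  stopifnot(all(vapply(cfg[1:4], function(v) v > 0, NA)),
            targets_per_drug[1] >= 10, alpha >= 0, sigma >= 0, sigma_dose >= 0)
  if (max(targets_per_drug) > n_genes)
    stop("infeasible config: more targets per drug than genes")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic drug/pathway/omics universe
#'
#' Gene sets are sampled without replacement from the gene universe. Each
#' drug has 1-3 "home" pathways from which ~70\% of its targets are drawn,
#' so drugs act coherently on pathways. MACCS-like fingerprint bits and
#' toxicity terms are Bernoulli draws. Each cell line has a sparse pathway
#' activity vector (a few strongly active pathways); omics values are built
#' from a per-gene baseline plus the summed activity of the pathways that
#' contain the gene, so pathway-level scoring of the omics recovers the
#' activity: EXP is raw TPM (log-normal), CNV a copy-number ratio near 1,
#' METHY a \[0, 1\] beta-like value with an NA mask, RNAi a Gaussian
#' dependency score with an NA mask, and mutations Bernoulli gene sets
#' enriched in active pathways. All output is seed-deterministic.
#'
#' @param config A [sim_config()].
#' @return List with `drugs` (drug table with list columns), `genesets`,
#'   `maccs_bits`, `omics` (named list of raw matrices with `assay`
#'   attributes), `mutations`, `activity` (cell x pathway matrix, the
#'   ground-truth pathway activity) and `config`.
#' @export
generate_universe <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  cells <- sprintf("CL%02d", seq_len(config$n_cell_lines))

  sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                  config$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
  genesets <- gene_set_collection(sets)

  drug_ids <- sprintf("D%02d", seq_len(config$n_drugs))
  targets <- lapply(seq_len(config$n_drugs), function(i) {
    home <- sample(names(sets), sample(1:3, 1L))
    pool <- unique(unlist(sets[home], use.names = FALSE))
    n_t <- sample(seq(config$targets_per_drug[1], config$targets_per_drug[2]), 1L)
    n_home <- min(length(pool), round(0.7 * n_t))
    t <- unique(c(sample(pool, n_home), sample(genes, n_t - n_home)))
    while (length(t) < config$targets_per_drug[1])
      t <- unique(c(t, sample(genes, 1L)))
    t
  })
  tox_terms <- sprintf("TOX%03d", seq_len(config$n_tox_terms))
  toxicity <- lapply(seq_len(config$n_drugs), function(i)
    tox_terms[stats::runif(config$n_tox_terms) < 0.15])
  drugs <- data.frame(drug_id = drug_ids, smiles = NA_character_,
                      target_genes = I(targets), toxicity_terms = I(toxicity),
                      stringsAsFactors = FALSE)

  maccs <- matrix(as.integer(stats::runif(config$n_drugs * 166) < 0.3),
                  config$n_drugs, 166,
                  dimnames = list(drug_ids, paste0("MACCS", 1:166)))

  # sparse per-cell pathway activity: ~5 strongly active pathways per cell
  act <- matrix(stats::rnorm(config$n_cell_lines * config$n_pathways, 0, 0.3),
                config$n_cell_lines, config$n_pathways,
                dimnames = list(cells, genesets$pathway_ids))
  for (cc in seq_len(config$n_cell_lines)) {
    on <- sample(config$n_pathways, min(5L, config$n_pathways))
    act[cc, on] <- stats::rnorm(length(on), 2.5, 0.5)
  }

  # per-gene pathway membership -> per (gene, cell) activity shift
  memb <- vapply(genesets$sets, function(p) as.numeric(genes %in% p),
                 numeric(config$n_genes))
  shift <- memb %*% t(act)          # genes x cells
  noise <- function(sd) matrix(stats::rnorm(config$n_genes *
                                              config$n_cell_lines, 0, sd),
                               config$n_genes, config$n_cell_lines)
  mu_exp <- stats::rnorm(config$n_genes, 3, 1)
  log2tpm <- pmax(mu_exp + 0.8 * shift + noise(0.3), 0)
  exp_tpm <- 2^log2tpm - 1
  cnv <- 2^(0.25 * shift / pmax(1, rowSums(memb)) + noise(0.15))
  methy <- stats::plogis(stats::rnorm(config$n_genes, -0.5, 0.8) +
                           0.5 * shift + noise(0.4))
  rnai <- -0.4 * shift + noise(0.5)
  mask <- function(m) {
    m[matrix(stats::runif(length(m)) < config$na_rate, nrow(m))] <- NA_real_
    m
  }
  dn <- list(genes, cells)
  omics <- list(
    EXP = structure(matrix(exp_tpm, config$n_genes, dimnames = dn),
                    assay = "EXP"),
    CNV = structure(matrix(cnv, config$n_genes, dimnames = dn),
                    assay = "CNV"),
    METHY = structure(mask(matrix(methy, config$n_genes, dimnames = dn)),
                      assay = "METHY"),
    RNAi = structure(mask(matrix(rnai, config$n_genes, dimnames = dn)),
                     assay = "RNAi"))

  p_mut <- 0.02 + 0.08 * stats::plogis(shift - 2)
  mut_draw <- matrix(stats::runif(length(p_mut)) < p_mut, nrow(p_mut))
  mutations <- lapply(seq_along(cells), function(j) genes[mut_draw[, j]])
  names(mutations) <- cells

  list(drugs = drugs, genesets = genesets, maccs_bits = maccs,
       omics = omics, mutations = mutations, activity = act, config = config)
}

#' Generate dose-response records with a planted pathway-mediated signal
#'
#' The planted synergy of a (pair, cell line) instance is
#' `alpha * z + sigma * noise`, where `z` is the standardised inner product
#' of the pair's combination-pathway score vector (the drug-pathway
#' indicator/Jaccard-refined construction) with the cell line's rectified
#' pathway activity — so the signal flows exactly through the features the
#' downstream model sees. Each instance emits `dose_points` records with
#' expected growth drawn per dose and observed growth = expected - synergy -
#' dose noise; averaging expected-minus-observed over doses therefore
#' recovers the planted synergy up to the mean dose noise. Optionally a few
#' single-agent rows are appended to exercise response cleaning.
#'
#' @param universe Output of [generate_universe()].
#' @param include_single_agent Append single-agent rows (default TRUE).
#' @return List with `records` (response data frame), `truth` (one row per
#'   instance with the planted synergy `s`) and `threshold` (the
#'   `label_quantile` quantile of the planted synergy).
#' @export
generate_responses <- function(universe, include_single_agent = TRUE) {
  cfg <- universe$config
  set.seed(cfg$seed + 1L)
  pairs <- all_drug_pairs(universe$drugs$drug_id)
  D <- build_drug_pathway_matrix(universe$drugs, universe$genesets)
  A <- build_combination_pathway_features(
    D, refine_drug_pathway(D, build_pathway_similarity(universe$genesets)),
    pairs)
  w <- pmax(universe$activity, 0)          # cells x pathways
  raw <- A %*% t(w)                        # pairs x cells
  z <- (raw - mean(raw)) / stats::sd(raw)
  cells <- rownames(universe$activity)
  truth <- data.frame(
    drug_a = rep(pairs$drug_a, times = length(cells)),
    drug_b = rep(pairs$drug_b, times = length(cells)),
    cell_line = rep(cells, each = nrow(pairs)),
    s = cfg$alpha * as.vector(z) +
      stats::rnorm(nrow(pairs) * length(cells), 0, cfg$sigma),
    stringsAsFactors = FALSE)
  n_inst <- nrow(truth)
  d <- cfg$dose_points
  expected <- stats::rnorm(n_inst * d, 60, 15)
  eta <- stats::rnorm(n_inst * d, 0, cfg$sigma_dose)
  records <- data.frame(
    drug_a = rep(truth$drug_a, each = d),
    drug_b = rep(truth$drug_b, each = d),
    cell_line = rep(truth$cell_line, each = d),
    expected_growth = expected,
    observed_growth = expected - rep(truth$s, each = d) - eta,
    stringsAsFactors = FALSE)
  if (include_single_agent) {
    sa <- data.frame(drug_a = universe$drugs$drug_id, drug_b = NA_character_,
                     cell_line = cells[1L],
                     expected_growth = stats::rnorm(nrow(universe$drugs), 60, 15),
                     observed_growth = stats::rnorm(nrow(universe$drugs), 60, 15),
                     stringsAsFactors = FALSE)
    records <- rbind(records, sa)
  }
  list(records = records, truth = truth,
       threshold = unname(stats::quantile(truth$s, cfg$label_quantile)))
}

#' Generate a replicate viability table with known combination score
#'
#' Eight replicates per arm are drawn Normal(arm mean, `sd`); the
#' closed-form score implied by the arm means is returned alongside.
#'
#' @param means Length-3 numeric: mean viability of monotherapy A,
#'   monotherapy B and the combination.
#' @param sd Replicate noise sd (0 gives the closed-form score exactly).
#' @param replicates Replicates per arm (default 8).
#' @param seed Integer RNG seed.
#' @return List with `arms` (named list of replicate vectors) and
#'   `true_score` (score implied by the arm means).
#' @export
generate_viability_table <- function(means = c(0.84, 0.77, 0.66), sd = 0.05,
                                     replicates = 8, seed = 1) {
  stopifnot(length(means) == 3L, all(means >= 0), sd >= 0, replicates >= 1L)
  set.seed(seed)
  arms <- lapply(means, function(m)
    pmax(stats::rnorm(replicates, m, sd), 0))
  names(arms) <- c("mono_a", "mono_b", "combo")
  best <- min(means[1:2])
  delta <- best - means[3]
  list(arms = arms, true_score = delta - delta * means[3] / best)
}

#' Write a complete synthetic study to disk
#'
#' Emits every file the pipeline reads: `drugs.tsv`, `pathways.gmt`,
#' `maccs.tsv`, `omics_EXP/CNV/METHY/RNAi.tsv`, `mutations.tsv`,
#' `responses.csv` and `truth.csv`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
simulate_study <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  uni <- generate_universe(config)
  resp <- generate_responses(uni)
  p <- function(f) file.path(dir, f)
  write_drug_table(uni$drugs, p("drugs.tsv"))
  write_gmt(uni$genesets, p("pathways.gmt"))
  write_omics_matrix(uni$maccs_bits, p("maccs.tsv"), id_col = "drug_id")
  for (a in names(uni$omics))
    write_omics_matrix(uni$omics[[a]], p(paste0("omics_", a, ".tsv")),
                       id_col = "gene")
  write_mutation_profiles(uni$mutations, p("mutations.tsv"))
  write_response_table(resp$records, p("responses.csv"))
  utils::write.csv(resp$truth, p("truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(list(drugs = p("drugs.tsv"), pathways = p("pathways.gmt"),
                 maccs = p("maccs.tsv"),
                 omics = stats::setNames(p(paste0("omics_", names(uni$omics), ".tsv")),
                                         names(uni$omics)),
                 mutations = p("mutations.tsv"),
                 responses = p("responses.csv"), truth = p("truth.csv")))
}
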
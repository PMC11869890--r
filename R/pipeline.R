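#' Build all eight feature blocks for a study
#'
#' Runs the full featurisation: density screening of drugs and pathways,
#' descriptor and toxicity-term filtering, pair-sum fingerprint and toxicity
#' blocks, the combination-pathway block, gene-set variation scores for the
#' continuous omics (with log2(x+1) transform for EXP/CNV and
#' NA-filter/KNN-impute for METHY/RNAi) and the mutation Jaccard block.
#' Pair blocks cover every unordered pair of the retained drugs.
#'
#' @param universe List with `drugs`, `genesets`, `maccs_bits`, `omics`,
#'   `mutations` (the shape produced by [generate_universe()], or assembled
#'   from files by the caller).
#' @param min_targets,min_genes,min_drug_fraction Screening thresholds (see
#'   [filter_drugs_and_pathways()]).
#' @param min_descriptor_drugs Descriptor retention threshold (see
#'   [filter_descriptors()]).
#' @param min_term_drugs Toxicity-term retention threshold.
#' @return List with `blocks` (the eight feature matrices, canonical
#'   order), `drugs` and `genesets` (post-screen), `pairs`.
#' @export
build_feature_blocks <- function(universe, min_targets = 10, min_genes = 10,
                                 min_drug_fraction = 0.5,
                                 min_descriptor_drugs = 10,
                                 min_term_drugs = 1) {
  scr <- filter_drugs_and_pathways(universe$drugs, universe$genesets,
                                   min_targets, min_genes, min_drug_fraction)
  drugs <- scr$drugs; genesets <- scr$genesets
  pairs <- all_drug_pairs(drugs$drug_id)

  bits <- universe$maccs_bits[drugs$drug_id, , drop = FALSE]
  kept_desc <- filter_descriptors(bits, min_descriptor_drugs)
  dd_maccs <- pair_sum_block(bits[, kept_desc, drop = FALSE], pairs)

  term_sets <- stats::setNames(drugs$toxicity_terms, drugs$drug_id)
  kept_terms <- filter_toxicity_terms(term_sets, min_term_drugs)
  dd_tox <- pair_sum_block(toxicity_matrix(term_sets, kept_terms), pairs)

  D <- build_drug_pathway_matrix(drugs, genesets)
  P <- build_pathway_similarity(genesets)
  ddp <- build_combination_pathway_features(D, refine_drug_pathway(D, P), pairs)

  blocks <- list(
    DD_MACCS = dd_maccs,
    DD_TOX = dd_tox,
    DDP = ddp,
    EXP = gsva_scores(t_unattr(transform_log2(universe$omics$EXP)), genesets),
    CNV = gsva_scores(t_unattr(transform_log2(universe$omics$CNV)), genesets),
    METHY = gsva_scores(t_unattr(filter_and_impute(universe$omics$METHY)),
                        genesets),
    MUT = mutation_pathway_jaccard(universe$mutations, genesets),
    RNAi = gsva_scores(t_unattr(filter_and_impute(universe$omics$RNAi)),
                       genesets))
  list(blocks = blocks, drugs = drugs, genesets = genesets, pairs = pairs)
}

# drop the assay attribute (gsva_scores takes a plain genes x cells matrix)
t_unattr <- function(m) {
  attr(m, "assay") <- NULL
  m
}

#' Label a response table and align it with the feature blocks
#'
#' Cleans the records (single-agent and excluded-drug rows), averages
#' expected-minus-observed growth per (pair, cell line), applies the
#' labelling threshold and keeps only instances whose drugs survived the
#' density screen.
#'
#' @param records Response records.
#' @param drugs Post-screen drug table.
#' @param threshold Labelling threshold on the combination score.
#' @param excluded_drug_ids Passed to [clean_response_records()].
#' @return Labelled instance data frame (`drug_a`, `drug_b`, `cell_line`,
#'   `comb_score`, `label`).
#' @export
label_instances <- function(records, drugs, threshold = 4,
                            excluded_drug_ids = "NSC753082") {
  cleaned <- clean_response_records(records, excluded_drug_ids, quiet = TRUE)
  cleaned <- cleaned[cleaned$drug_a %in% drugs$drug_id &
                       cleaned$drug_b %in% drugs$drug_id, , drop = FALSE]
  assign_labels(comb_score(cleaned), threshold)
}
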
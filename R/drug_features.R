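#' Compute the 166-key MACCS fingerprint of a molecule
#'
#' Structural drug features use the standard 166-key MACCS substructure
#' dictionary; each position flags presence of a predefined chemical feature
#' (e.g. S-S, N-O, C=CN). Keys are computed with OpenBabel through
#' \pkg{ChemmineOB}. Note that toolkits can disagree on a handful of
#' aromaticity-dependent keys for fused heteroaromatic ring systems; simple
#' molecules agree bit-for-bit with other toolkits.
#'
#' @param smiles A single SMILES string.
#' @return Named integer 0/1 vector of length 166 (names `MACCS1`..`MACCS166`).
#' @export
compute_maccs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  fp <- tryCatch(
    suppressWarnings({
      ob <- ChemmineOB::forEachMol("SMILES", smiles, identity)
      ChemmineOB::fingerprint_OB(ob, "MACCS")
    }),
    error = function(e) NULL)
  v <- if (is.null(fp)) numeric(0) else as.vector(fp)
  # OpenBabel pads MACCS to 256 bits; positions 1..166 carry the keys.
  if (length(v) < 166L || (sum(v[seq_len(166L)]) == 0 && !smiles %in% c("[H][H]")))
    stop("could not parse SMILES for fingerprinting: '", smiles, "'")
  out <- as.integer(v[seq_len(166L)] != 0)
  names(out) <- paste0("MACCS", seq_len(166L))
  out
}

#' Build a drug x MACCS-key 0/1 matrix from SMILES
#'
#' @param drugs Drug table (see [read_drug_table()]); rows without a SMILES
#'   are dropped with a warning.
#' @return Integer matrix, drugs x 166 keys.
#' @export
maccs_matrix <- function(drugs) {
  ok <- !is.na(drugs$smiles)
  if (any(!ok))
    warning(sum(!ok), " drug(s) without SMILES dropped from MACCS matrix")
  rows <- lapply(drugs$smiles[ok], compute_maccs)
  m <- do.call(rbind, rows)
  rownames(m) <- drugs$drug_id[ok]
  m
}

#' Retain fingerprint descriptors present in enough drugs
#'
#' A descriptor column survives when it is set in at least `min_drugs` drugs
#' (inclusive); column order is preserved. Filtering is done on the
#' single-drug matrix before any pair encoding.
#'
#' @param bits Drug x descriptor 0/1 matrix.
#' @param min_drugs Minimum number of drugs a descriptor must be set in.
#' @return Character vector of retained column names.
#' @export
filter_descriptors <- function(bits, min_drugs = 10) {
  stopifnot(is.matrix(bits), nrow(bits) >= 1L)
  keep <- colSums(bits != 0) >= min_drugs
  colnames(bits)[keep]
}

#' Retain toxicity terms attached to enough drugs
#'
#' @param term_sets Named list: drug -> character vector of toxicity term ids.
#' @param min_drugs Minimum number of drugs per retained term (default 1:
#'   every term with at least one drug survives).
#' @return Character vector of retained term ids, in first-appearance order.
#' @export
filter_toxicity_terms <- function(term_sets, min_drugs = 1) {
  stopifnot(length(term_sets) >= 1L)
  all_terms <- unlist(term_sets, use.names = FALSE)
  terms <- unique(all_terms)
  counts <- vapply(terms, function(t)
    sum(vapply(term_sets, function(s) t %in% s, NA)), 1L)
  terms[counts >= min_drugs]
}

#' Build a drug x toxicity-term 0/1 matrix
#'
#' Drugs with no retained term get an all-zero row.
#'
#' @param term_sets Named list: drug -> toxicity term ids.
#' @param terms Retained term ids defining the column order.
#' @return Integer matrix, drugs x terms.
#' @export
toxicity_matrix <- function(term_sets, terms) {
  m <- vapply(terms, function(t)
    as.integer(vapply(term_sets, function(s) t %in% s, NA)),
    integer(length(term_sets)))
  m <- matrix(m, nrow = length(term_sets),
              dimnames = list(names(term_sets), terms))
  m
}

#' Encode a drug pair as the elementwise sum of two bit vectors
#'
#' Entry values read: 0 = neither drug has the feature, 1 = exactly one
#' drug has it, 2 = both do. The encoding is commutative.
#'
#' @param vec_a,vec_b Equal-length 0/1 vectors with identical names.
#' @return Integer vector of sums in \{0, 1, 2\}.
#' @export
encode_pair_sum <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b) ||
      !identical(names(vec_a), names(vec_b)))
    stop("pair encoding requires identical descriptor positions")
  as.integer(vec_a) + as.integer(vec_b)
}

#' Build a pair feature block by summed bit vectors
#'
#' @param bits Drug x descriptor 0/1 matrix (already column-filtered).
#' @param pairs Data frame or 2-column matrix of drug ids.
#' @return Numeric matrix, one row per pair (rownames `a|b`, canonical
#'   sorted order), columns as in `bits`.
#' @export
pair_sum_block <- function(bits, pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  unknown <- setdiff(unique(c(pairs)), rownames(bits))
  if (length(unknown)) stop("unknown drug in pair list: ", unknown[1L])
  key <- pair_key(pairs[, 1L], pairs[, 2L])
  out <- bits[pairs[, 1L], , drop = FALSE] + bits[pairs[, 2L], , drop = FALSE]
  rownames(out) <- key
  out
}

#' Canonical key for an unordered drug pair
#'
#' @param a,b Drug id vectors.
#' @return Character vector `min|max` per pair.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
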
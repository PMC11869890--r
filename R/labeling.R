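#' Clean a dose-response table before labelling
#'
#' Drops single-agent rows (absent `drug_b`) and every row touching an
#' excluded drug id. The default exclusion removes NSC753082, one of two
#' catalogue ids for vinorelbine in the NCI-ALMANAC screen, so the alias is
#' counted once; the list is configurable rather than hard-coded chemistry.
#'
#' @param records Response records (see [read_response_table()]).
#' @param excluded_drug_ids Drug ids whose rows are dropped entirely.
#' @param quiet Suppress the removed-row message.
#' @return Filtered records.
#' @export
clean_response_records <- function(records,
                                   excluded_drug_ids = "NSC753082",
                                   quiet = FALSE) {
  single <- is.na(records$drug_b)
  excl <- records$drug_a %in% excluded_drug_ids |
    (!single & records$drug_b %in% excluded_drug_ids)
  keep <- !single & !excl
  if (!quiet)
    message("clean_response_records: dropped ", sum(single),
            " single-agent and ", sum(excl & !single),
            " excluded-drug row(s); ", sum(keep), " retained")
  records[keep, , drop = FALSE]
}

#' Combination score per (drug pair, cell line)
#'
#' The combination score is the mean over dose points of (expected growth -
#' observed percent growth); dose identity is ignored. Positive values mean
#' the pair suppressed growth more than the expected (reference-model)
#' response, i.e. acted synergistically. The pair key is canonical
#' (lexicographically sorted), so swapping `drug_a`/`drug_b` and reordering
#' dose rows do not change the result.
#'
#' @param records Cleaned response records (no single-agent rows).
#' @return Data frame: `drug_a`, `drug_b` (canonical order), `cell_line`,
#'   `comb_score`, `n_doses`.
#' @export
comb_score <- function(records) {
  if (nrow(records) == 0L) stop("no response records to score")
  if (anyNA(records$drug_b)) stop("single-agent rows present; clean first")
  a <- pmin(records$drug_a, records$drug_b)
  b <- pmax(records$drug_a, records$drug_b)
  key <- paste(a, b, records$cell_line, sep = "\r")
  diff <- records$expected_growth - records$observed_growth
  agg <- rowsum(cbind(diff = diff, n = 1), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(drug_a = parts[, 1L], drug_b = parts[, 2L],
                    cell_line = parts[, 3L],
                    comb_score = agg[, "diff"] / agg[, "n"],
                    n_doses = as.integer(agg[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$drug_a, out$drug_b, out$cell_line), , drop = FALSE]
}

#' Binary synergy labels from combination scores
#'
#' A (pair, cell line) instance is synergistic (label 1) when its
#' combination score is strictly greater than the threshold; a score exactly
#' at the threshold is non-synergistic. Thresholds of 4 and 10 are the two
#' conventional operating points for percent-growth screens.
#'
#' @param scores Output of [comb_score()].
#' @param threshold Real labelling threshold (default 4).
#' @return `scores` with added columns `threshold` and `label` (0/1 integer).
#' @export
assign_labels <- function(scores, threshold = 4) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  scores$threshold <- threshold
  scores$label <- as.integer(scores$comb_score > threshold)
  scores
}
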
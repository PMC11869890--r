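#' Log2(x + 1) transform of an abundance matrix
#'
#' Applied to TPM expression values and to copy-number ratios, both of which
#' are non-negative by construction.
#'
#' @param m Numeric matrix, assay `EXP` or `CNV`, no negative entries.
#' @return Transformed matrix; the `assay` attribute is preserved.
#' @export
transform_log2 <- function(m) {
  assay <- attr(m, "assay")
  if (!is.null(assay) && !assay %in% c("EXP", "CNV"))
    stop("log2(x+1) transform applies to EXP and CNV assays, not ", assay)
  if (anyNA(m)) stop("log2 transform input must be complete")
  if (any(m < 0)) stop("log2(x+1) transform requires non-negative values")
  out <- log2(m + 1)
  attr(out, "assay") <- assay
  out
}

#' NA-filter, KNN-impute and probe-collapse a methylation/RNAi matrix
#'
#' Three steps, in order:
#' \enumerate{
#'   \item drop rows with an NA fraction strictly greater than
#'     `max_na_fraction`;
#'   \item impute each remaining NA at (row g, column c) as the mean value at
#'     column c of the `k` rows nearest to g. Distance between two rows is
#'     the root mean squared difference over their jointly observed columns
#'     (scaling by the count of such columns keeps rows with different
#'     missingness comparable); only rows observed at column c are candidate
#'     neighbours;
#'   \item average rows mapping to the same gene id (probe-to-gene collapse),
#'     per column.
#' }
#' Observed entries pass through bit-exactly.
#'
#' @param m Numeric matrix (probes/genes x cell lines), NAs allowed.
#' @param max_na_fraction Strict row-wise NA-fraction cutoff (default 0.7).
#' @param k Number of nearest neighbour rows used per imputation.
#' @param gene_map Optional named character vector mapping row ids to gene
#'   ids; by default rows sharing a rowname are collapsed.
#' @return Numeric matrix, genes x cell lines, no NAs; `assay` preserved.
#' @export
filter_and_impute <- function(m, max_na_fraction = 0.7, k = 5, gene_map = NULL) {
  assay <- attr(m, "assay")
  if (!is.null(assay) && !assay %in% c("METHY", "RNAi"))
    stop("filter_and_impute applies to METHY and RNAi assays, not ", assay)
  na_frac <- rowMeans(is.na(m))
  m <- m[na_frac <= max_na_fraction, , drop = FALSE]
  if (nrow(m) == 0L) stop("all rows removed by the NA-fraction filter")
  if (any(rowSums(!is.na(m)) == 0L))
    stop("row with zero observed entries survived the NA filter")
  filled <- m
  if (anyNA(m)) {
    for (g in which(rowSums(is.na(m)) > 0L)) {
      for (cc in which(is.na(m[g, ]))) {
        cand <- setdiff(which(!is.na(m[, cc])), g)
        if (length(cand) == 0L)
          stop("cannot impute column ", colnames(m)[cc],
               ": no observed neighbour rows")
        d <- vapply(cand, function(r) {
          joint <- !is.na(m[g, ]) & !is.na(m[r, ])
          if (!any(joint)) return(Inf)
          sqrt(mean((m[g, joint] - m[r, joint])^2))
        }, 0)
        near <- cand[order(d)][seq_len(min(k, length(cand)))]
        filled[g, cc] <- mean(m[near, cc])
      }
    }
  }
  ids <- if (is.null(gene_map)) rownames(filled) else unname(gene_map[rownames(filled)])
  if (anyDuplicated(ids)) {
    groups <- split(seq_along(ids), factor(ids, levels = unique(ids)))
    out <- t(vapply(groups, function(ix)
      colMeans(filled[ix, , drop = FALSE]), numeric(ncol(filled))))
    colnames(out) <- colnames(filled)
  } else {
    out <- filled
    rownames(out) <- ids
  }
  attr(out, "assay") <- assay
  out
}

#' Single-sample gene-set variation scores per cell line
#'
#' A gene-set variation analysis for continuous omics values: each gene's
#' values are mapped through a Gaussian-kernel CDF estimate across cell
#' lines (bandwidth sd/4, floored to survive constant rows), genes are
#' ranked per cell line and given symmetric rank weights, and each gene set
#' is scored by the maximum deviation of a weighted Kolmogorov-Smirnov
#' random walk down the ranked list. Scores lie in \[-1, 1\]. When the
#' positive and negative extremes of the walk tie in magnitude the negative
#' one is taken.
#'
#' @param m Numeric matrix, genes x cell lines (>= 2 columns), complete.
#' @param genesets A `gene_set_collection`; sets are intersected with the
#'   matrix rows, and a set with empty intersection scores 0 with a warning.
#' @param tau Rank-weight exponent of the random walk (default 1).
#' @return Numeric matrix, cell lines x pathways (collection order).
#' @export
gsva_scores <- function(m, genesets, tau = 1) {
  stopifnot(inherits(genesets, "gene_set_collection"), is.matrix(m))
  if (ncol(m) < 2L) stop("gene-set variation scores need >= 2 cell lines")
  if (anyNA(m)) stop("omics matrix must be imputed before scoring")
  N <- nrow(m); M <- ncol(m)
  rng <- diff(range(m))
  z <- matrix(0, N, M)
  for (i in seq_len(N)) {
    h <- max(stats::sd(m[i, ]) / 4, 1e-8 * rng, .Machine$double.eps)
    z[i, ] <- vapply(seq_len(M), function(j)
      mean(stats::pnorm((m[i, j] - m[i, ]) / h)), 0)
  }
  weights_sorted <- abs(seq(N, 1) - N / 2)
  es <- matrix(0, M, length(genesets$sets),
               dimnames = list(colnames(m), genesets$pathway_ids))
  member <- lapply(genesets$sets, function(p) rownames(m) %in% p)
  empty <- !vapply(member, any, NA)
  if (any(empty))
    warning("gene set(s) with no genes in the matrix score 0: ",
            paste(genesets$pathway_ids[empty], collapse = ", "))
  for (j in seq_len(M)) {
    ord <- order(z[, j], decreasing = TRUE)
    for (k in seq_along(member)) {
      if (empty[k]) next
      inset <- member[[k]][ord]
      w <- weights_sorted^tau
      step_in <- ifelse(inset, w, 0)
      n_out <- N - sum(inset)
      nu <- cumsum(step_in) / sum(step_in) -
        cumsum(!inset) / n_out
      mx <- max(nu, 0); mn <- min(nu, 0)
      es[j, k] <- if (mx > -mn) mx else mn
    }
  }
  es
}

#' Mutation-pathway Jaccard scores per cell line
#'
#' Score(cell, pathway) = |mutated intersect pathway| / |mutated union
#' pathway|. A cell line with no mutated genes scores 0 on every pathway
#' (empty intersection over a non-empty union).
#'
#' @param profiles Named list: cell line -> mutated-gene character vector.
#' @param genesets A `gene_set_collection`.
#' @return Numeric matrix, cell lines x pathways, values in \[0, 1\].
#' @export
mutation_pathway_jaccard <- function(profiles, genesets) {
  stopifnot(inherits(genesets, "gene_set_collection"), length(profiles) > 0L)
  out <- matrix(0, length(profiles), length(genesets$sets),
                dimnames = list(names(profiles), genesets$pathway_ids))
  for (i in seq_along(profiles)) {
    mut <- unique(profiles[[i]])
    for (k in seq_along(genesets$sets)) {
      p <- genesets$sets[[k]]
      inter <- length(intersect(mut, p))
      out[i, k] <- inter / (length(mut) + length(p) - inter)
    }
  }
  out
}
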
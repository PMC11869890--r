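#' Screen drugs and pathways for matrix density
#'
#' One screening pass in three steps: (i) drop drugs with fewer than
#' `min_targets` target genes; (ii) drop pathways with fewer than `min_genes`
#' genes; (iii) drop pathways on which fewer than `min_drug_fraction` of the
#' *retained* drugs act, where a drug acts on a pathway iff its target set
#' intersects the pathway's gene set. All boundaries are inclusive ("at
#' least"). Input orders are preserved. The screen is a single pass, not
#' iterated to a fixpoint.
#'
#' @param drugs Drug table (see [read_drug_table()]).
#' @param genesets A `gene_set_collection`.
#' @param min_targets Minimum target-gene count per retained drug.
#' @param min_genes Minimum gene count per retained pathway.
#' @param min_drug_fraction Minimum fraction of retained drugs acting on a
#'   retained pathway.
#' @return List with elements `drugs` (filtered drug table) and `genesets`
#'   (filtered `gene_set_collection`).
#' @export
filter_drugs_and_pathways <- function(drugs, genesets, min_targets = 10,
                                      min_genes = 10, min_drug_fraction = 0.5) {
  stopifnot(inherits(genesets, "gene_set_collection"), nrow(drugs) > 0L)
  keep_d <- lengths(drugs$target_genes) >= min_targets
  drugs2 <- drugs[keep_d, , drop = FALSE]
  if (nrow(drugs2) == 0L) stop("all drugs removed by the target-count screen")
  sets <- genesets$sets[lengths(genesets$sets) >= min_genes]
  if (length(sets) == 0L) stop("all pathways removed by the gene-count screen")
  n_acting <- vapply(sets, function(p)
    sum(vapply(drugs2$target_genes, function(t) any(t %in% p), NA)), 1L)
  sets <- sets[n_acting / nrow(drugs2) >= min_drug_fraction]
  if (length(sets) == 0L) stop("all pathways removed by the drug-coverage screen")
  list(drugs = drugs2, genesets = gene_set_collection(sets))
}

#' Drug-pathway indicator matrix
#'
#' Entry (i, j) is 1 when drug i's target-gene set intersects pathway j's
#' gene set, else 0: the binary map of which pathways each drug acts on.
#'
#' @param drugs Drug table (screened).
#' @param genesets A `gene_set_collection` (screened).
#' @return Numeric 0/1 matrix, drugs x pathways.
#' @export
build_drug_pathway_matrix <- function(drugs, genesets) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  D <- vapply(genesets$sets, function(p)
    as.numeric(vapply(drugs$target_genes, function(t) any(t %in% p), NA)),
    numeric(nrow(drugs)))
  D <- matrix(D, nrow = nrow(drugs),
              dimnames = list(drugs$drug_id, genesets$pathway_ids))
  D
}

#' Pathway-pathway Jaccard similarity matrix
#'
#' Entry (i, j) is |p_i intersect p_j| / |p_i union p_j| over gene sets;
#' symmetric with unit diagonal.
#'
#' @param genesets A `gene_set_collection`.
#' @return Numeric matrix, pathways x pathways, values in \[0, 1\].
#' @export
build_pathway_similarity <- function(genesets) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  sets <- genesets$sets
  n <- length(sets)
  P <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        P[i, j] <- P[j, i] <- inter /
          (length(sets[[i]]) + length(sets[[j]]) - inter)
      }
    }
  }
  dimnames(P) <- list(genesets$pathway_ids, genesets$pathway_ids)
  P
}

#' Refine drug-pathway scores by pathway similarity
#'
#' The refined matrix is the product of the indicator matrix and the
#' pathway-similarity matrix, so a drug receives credit on a pathway both
#' for acting on it directly and for acting on similar pathways. Because the
#' similarity diagonal is 1 and all terms are non-negative, every refined
#' entry dominates the corresponding indicator entry.
#'
#' @param D Drug-pathway indicator matrix.
#' @param P Pathway-similarity matrix.
#' @return Numeric matrix, drugs x pathways.
#' @export
refine_drug_pathway <- function(D, P) {
  if (ncol(D) != nrow(P)) stop("non-conformable: ncol(D) != nrow(P)")
  D %*% P
}

#' Symmetric drug-combination pathway scores
#'
#' For drugs i, j and pathway k the combination score is
#' `(d_ik * dref_jk + d_jk * dref_ik) / 2`, where `d` is the indicator
#' matrix and `dref` its similarity-refined counterpart. The score is
#' symmetric in the two drugs and zero whenever neither drug acts on the
#' pathway. One row per unordered pair; this is the DDP feature block.
#'
#' @param D Drug-pathway indicator matrix.
#' @param D_refined Refined drug-pathway matrix (same dimnames as `D`).
#' @param pairs Data frame or 2-column matrix of drug ids.
#' @return Numeric matrix, pairs x pathways; rownames are canonical
#'   `a|b` pair keys.
#' @export
build_combination_pathway_features <- function(D, D_refined, pairs) {
  stopifnot(identical(dimnames(D), dimnames(D_refined)))
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  unknown <- setdiff(unique(c(pairs)), rownames(D))
  if (length(unknown)) stop("pair references unknown drug: ", unknown[1L])
  a <- pairs[, 1L]; b <- pairs[, 2L]
  out <- (D[a, , drop = FALSE] * D_refined[b, , drop = FALSE] +
          D[b, , drop = FALSE] * D_refined[a, , drop = FALSE]) / 2
  rownames(out) <- pair_key(a, b)
  out
}

#' All unordered drug pairs
#'
#' @param drug_ids Character vector of drug ids.
#' @return Data frame with columns `drug_a`, `drug_b` (lexicographically
#'   canonical within each row), one row per unordered pair.
#' @export
all_drug_pairs <- function(drug_ids) {
  drug_ids <- sort(unique(drug_ids))
  idx <- utils::combn(length(drug_ids), 2L)
  data.frame(drug_a = drug_ids[idx[1L, ]], drug_b = drug_ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}
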
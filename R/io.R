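#' Read a gene-set collection from a GMT file
#'
#' Each line of a GMT file is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Pathway order is taken from file order and is used as the column order of
#' every pathway-indexed matrix produced downstream.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets` (named list of character vectors, duplicates within a set
#'   removed), `pathway_ids` (character, file order) and `gene_universe`
#'   (character, union of all genes).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file '", path, "' contains no gene sets")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], ": expected at least 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway name in GMT: ", ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  empty <- !vapply(sets, length, 1L)
  if (any(empty))
    stop("pathway '", ids[empty][1L], "' has an empty gene list")
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors; names are pathway ids.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("pathway ids must be unique")
  if (any(!vapply(sets, length, 1L))) stop("every gene set must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(
    list(sets = sets,
         pathway_ids = names(sets),
         gene_universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Gene-set collection:", length(x$sets), "pathways,",
      length(x$gene_universe), "genes\n")
  cat("  set sizes:", min(sizes), "-", max(sizes),
      "(median", stats::median(sizes), ")\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(gsc$pathway_ids, function(id)
    paste(c(id, "na", gsc$sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a drug table
#'
#' TSV with header columns `drug_id`, `smiles`, `targets`, `toxicity`;
#' `targets` and `toxicity` are `|`-joined identifier lists (may be empty).
#'
#' @param path Path to TSV.
#' @return A data frame with columns `drug_id` (character), `smiles`
#'   (character, `NA` when absent) and list columns `target_genes`,
#'   `toxicity_terms`.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  need <- c("drug_id", "smiles", "targets", "toxicity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug_id: ", df$drug_id[duplicated(df$drug_id)][1L])
  split_bar <- function(s) lapply(s, function(v)
    if (!nzchar(v)) character(0) else unique(strsplit(v, "|", fixed = TRUE)[[1L]]))
  data.frame(drug_id = df$drug_id,
             smiles = ifelse(nzchar(df$smiles), df$smiles, NA_character_),
             target_genes = I(split_bar(df$targets)),
             toxicity_terms = I(split_bar(df$toxicity)),
             stringsAsFactors = FALSE)
}

#' Write a drug table
#'
#' @param drugs Drug data frame as returned by [read_drug_table()].
#' @param path Output path.
#' @export
write_drug_table <- function(drugs, path) {
  join <- function(col) vapply(col, paste, "", collapse = "|")
  out <- data.frame(drug_id = drugs$drug_id,
                    smiles = ifelse(is.na(drugs$smiles), "", drugs$smiles),
                    targets = join(drugs$target_genes),
                    toxicity = join(drugs$toxicity_terms))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table
#'
#' CSV with header columns `drug_a`, `drug_b`, `cell_line`,
#' `expected_growth`, `observed_growth`, one row per dose point. An empty
#' `drug_b` marks a single-agent row (kept here; dropped by
#' [clean_response_records()]). Growth values are percent-growth reals and
#' are not range-clamped.
#'
#' @param path Path to CSV.
#' @return Data frame with `drug_b` as `NA` for single-agent rows.
#' @export
read_response_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  need <- c("drug_a", "drug_b", "cell_line", "expected_growth", "observed_growth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("response table missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (nrow(df) && length(bad))
      stop("non-numeric or non-finite ", name, " at data row ", bad[1L])
    v
  }
  data.frame(drug_a = df$drug_a,
             drug_b = ifelse(nzchar(df$drug_b), df$drug_b, NA_character_),
             cell_line = df$cell_line,
             expected_growth = num("expected_growth", "expected_growth"),
             observed_growth = num("observed_growth", "observed_growth"),
             stringsAsFactors = FALSE)
}

#' Write a dose-response table
#'
#' @param records Response records (see [read_response_table()]).
#' @param path Output path.
#' @export
write_response_table <- function(records, path) {
  out <- records
  out$drug_b <- ifelse(is.na(out$drug_b), "", out$drug_b)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an omics matrix
#'
#' TSV whose first column holds feature (gene or probe) ids and remaining
#' columns cell lines. The literal token `NA` is accepted as missing only
#' for `METHY` and `RNAi` (pre-imputation); `EXP` and `CNV` must be complete.
#'
#' @param path Path to TSV.
#' @param assay One of `"EXP"`, `"CNV"`, `"METHY"`, `"RNAi"`.
#' @return Numeric matrix (features x cell lines) with attribute `assay`.
#' @export
read_omics_matrix <- function(path, assay = c("EXP", "CNV", "METHY", "RNAi")) {
  assay <- match.arg(assay)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (ncol(df) < 2L) stop("omics TSV needs a row-id column plus >=1 cell line")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate row id: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(names(df)[-1L])) stop("duplicate cell-line column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  isna <- m == "NA"
  vals <- suppressWarnings(as.numeric(m))
  if (any(!isna & is.na(vals)))
    stop("non-numeric value in omics matrix '", path, "'")
  vals[isna] <- NA_real_
  if (assay %in% c("EXP", "CNV") && anyNA(vals))
    stop("NA values are not allowed in ", assay, " matrices")
  out <- matrix(vals, nrow = nrow(m),
                dimnames = list(ids, colnames(df)[-1L]))
  attr(out, "assay") <- assay
  out
}

#' Write an omics (or any feature) matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header for the row-id column.
#' @export
write_omics_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell-line mutated-gene sets
#'
#' TSV with columns `cell_line` and `genes` (`|`-joined; may be empty).
#'
#' @param path Path to TSV.
#' @return Named list: cell line -> character vector of mutated genes.
#' @export
read_mutation_profiles <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  miss <- setdiff(c("cell_line", "genes"), names(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_line)) stop("duplicate cell_line in mutation table")
  out <- lapply(df$genes, function(v)
    if (!nzchar(v)) character(0) else unique(strsplit(v, "|", fixed = TRUE)[[1L]]))
  names(out) <- df$cell_line
  out
}

#' Write per-cell-line mutated-gene sets
#'
#' @param profiles Named list of character vectors.
#' @param path Output path.
#' @export
write_mutation_profiles <- function(profiles, path) {
  out <- data.frame(cell_line = names(profiles),
                    genes = vapply(profiles, paste, "", collapse = "|"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write model predictions
#'
#' Rows are sorted lexicographically by (`drug_a`, `drug_b`, `cell_line`) so
#' output is deterministic regardless of input order.
#'
#' @param instances Data frame with `drug_a`, `drug_b`, `cell_line`.
#' @param scores Numeric prediction scores, aligned with `instances`.
#' @param labels 0/1 predicted labels, aligned with `instances`.
#' @param path Output path (CSV).
#' @export
write_predictions <- function(instances, scores, labels, path) {
  if (nrow(instances) != length(scores) || length(scores) != length(labels))
    stop("instances, scores and labels must have equal length")
  out <- data.frame(drug_a = instances$drug_a, drug_b = instances$drug_b,
                    cell_line = instances$cell_line,
                    score = scores, predicted_label = labels)
  out <- out[order(out$drug_a, out$drug_b, out$cell_line), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicate viability table
#'
#' CSV with columns `arm`, `replicate_index`, `viability` (fraction of the
#' untreated control; 1.0 = control level, values above 1 are retained).
#'
#' @param path Path to CSV.
#' @return Named list: arm -> numeric replicate viabilities.
#' @export
read_viability_table <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("arm", "replicate_index", "viability"), names(df))
  if (length(miss)) stop("viability table missing column(s): ",
                         paste(miss, collapse = ", "))
  v <- as.numeric(df$viability)
  if (any(!is.finite(v)) || any(v < 0))
    stop("viabilities must be finite and non-negative")
  split(v, factor(df$arm, levels = unique(df$arm)))
}
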
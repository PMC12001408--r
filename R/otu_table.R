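#' OTU count table
#'
#' Container for an integer abundance matrix (samples x OTUs) with optional
#' per-OTU taxonomy labels.  Rows are samples, columns are OTUs; both are kept
#' in canonical (lexicographic, C-collation) id order so that every downstream
#' statistic is invariant to the row order of the input files.
#'
#' @param counts numeric matrix of non-negative integers with unique rownames
#'   (sample ids) and colnames (OTU ids).
#' @param taxonomy optional named character vector mapping OTU ids to lineage
#'   strings; every name must be a column of `counts`.
#' @return An object of class `otu_counts`: the canonical-ordered integer
#'   matrix with a `taxonomy` attribute.
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 0L, 0L, 4L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
#' tab <- otu_counts(m)
#' total_reads(tab)
#' @export
otu_counts <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    ur_stop("counts must have sample ids as rownames and OTU ids as colnames",
            "urostab_validation_error")
  bad <- which(!is_wholenumber(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ur_stop(sprintf(
      "non-integer or negative count at sample '%s', OTU '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])),
      "urostab_format_error")
  }
  if (anyDuplicated(rownames(counts)))
    ur_stop(paste0("duplicate sample ids: ",
                   fmt_ids(unique(rownames(counts)[duplicated(rownames(counts))]))),
            "urostab_validation_error")
  if (anyDuplicated(colnames(counts)))
    ur_stop(paste0("duplicate OTU ids: ",
                   fmt_ids(unique(colnames(counts)[duplicated(colnames(counts))]))),
            "urostab_validation_error")
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      ur_stop("taxonomy must be a named character vector", "urostab_validation_error")
    unknown <- setdiff(names(taxonomy), colnames(counts))
    if (length(unknown) > 0)
      ur_stop(paste0("taxonomy refers to unknown OTU ids: ", fmt_ids(unknown)),
              "urostab_validation_error")
    taxonomy <- taxonomy[id_order(names(taxonomy))]
  }
  storage.mode(counts) <- "integer"
  counts <- counts[id_order(rownames(counts)), id_order(colnames(counts)), drop = FALSE]
  structure(counts, taxonomy = taxonomy, class = c("otu_counts", "matrix", "array"))
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("OTU count table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  tx <- attr(x, "taxonomy")
  if (!is.null(tx)) cat(sprintf("taxonomy labels for %d OTUs\n", length(tx)))
  invisible(x)
}

# subsetting keeps the class and prunes taxonomy to retained OTUs
#' @export
`[.otu_counts` <- function(x, i, j, ..., drop = TRUE) {
  tx <- attr(x, "taxonomy")
  m <- unclass(x)
  attr(m, "taxonomy") <- NULL
  if (nargs() <= 2 && missing(j)) return(m[i])   # linear/matrix-index access
  out <- m[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  if (!is.null(tx)) tx <- tx[names(tx) %in% colnames(out)]
  structure(out, taxonomy = tx, class = c("otu_counts", "matrix", "array"))
}

#' Total reads per sample
#'
#' @param x an `otu_counts` table.
#' @return Named integer vector of per-sample read totals.
#' @export
total_reads <- function(x) {
  stopifnot(inherits(x, "otu_counts"))
  rowSums(x)
}

#' Taxonomy labels of an OTU table
#'
#' @param x an `otu_counts` table.
#' @return Named character vector (possibly `NULL`).
#' @export
taxonomy <- function(x) attr(x, "taxonomy")

#' Read an OTU count table
#'
#' Two plain-text dialects are supported.  `tsv_dense`: rows are OTUs, the
#' first column holds OTU ids and the header row holds sample ids (the layout
#' in which processed amplicon tables are usually deposited).  `triplet_sparse`:
#' one `(otu_id, sample_id, count)` row per nonzero cell, BIOM-style.  Both
#' dialects produce the identical canonical table for the same data.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @param dialect `"tsv_dense"` or `"triplet_sparse"`.
#' @param col_map optional named character vector remapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(otu_id = "#OTU ID", sample_id = "Sample", count = "reads")` for the
#'   sparse dialect or `c(otu_id = "#OTU ID")` for the dense one.  This is how
#'   externally deposited tables with other headers are read.
#' @param taxonomy optional path to a two-column TSV (`otu_id`, `lineage`).
#' @return An [otu_counts] table.  Zero rows/columns present in a dense file
#'   are retained, never dropped.
#' @export
read_otu_table <- function(path, dialect = c("tsv_dense", "triplet_sparse"),
                           col_map = NULL, taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ur_stop(paste0("file not found: ", path), "urostab_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tx <- if (!is.null(taxonomy)) read_taxonomy(taxonomy) else NULL

  if (dialect == "tsv_dense") {
    idcol <- unname(col_map["otu_id"] %||% colnames(df)[1])
    if (is.na(idcol) || !idcol %in% colnames(df))
      ur_stop(paste0("dense dialect: OTU id column '", idcol, "' not found"),
              "urostab_format_error")
    otu_ids <- as.character(df[[idcol]])
    m <- as.matrix(df[setdiff(colnames(df), idcol)])
    check_integer_cells(m, otu_ids, path)
    storage.mode(m) <- "integer"
    counts <- t(m)                      # internal layout: samples x OTUs
    colnames(counts) <- otu_ids
    return(otu_counts(counts, taxonomy = tx))
  }

  # triplet_sparse
  need <- c(otu_id = "otu_id", sample_id = "sample_id", count = "count")
  if (!is.null(col_map)) need[names(col_map)] <- col_map
  missing_cols <- setdiff(unname(need), colnames(df))
  if (length(missing_cols) > 0)
    ur_stop(paste0("triplet dialect: missing columns: ", fmt_ids(missing_cols)),
            "urostab_format_error")
  otu <- as.character(df[[need["otu_id"]]])
  smp <- as.character(df[[need["sample_id"]]])
  cnt <- df[[need["count"]]]
  bad <- which(!is_wholenumber(suppressWarnings(as.numeric(cnt))) |
                 suppressWarnings(as.numeric(cnt)) < 0)
  if (length(bad) > 0)
    ur_stop(sprintf("non-integer or negative count '%s' at row %d (otu '%s', sample '%s')",
                    cnt[bad[1]], bad[1], otu[bad[1]], smp[bad[1]]),
            "urostab_format_error")
  if (anyDuplicated(paste0(otu, "\r", smp)))
    ur_stop("duplicate (otu_id, sample_id) pairs in triplet file",
            "urostab_validation_error")
  otu_ids <- sort(unique(otu), method = "radix")
  sample_ids <- sort(unique(smp), method = "radix")
  counts <- matrix(0L, nrow = length(sample_ids), ncol = length(otu_ids),
                   dimnames = list(sample_ids, otu_ids))
  counts[cbind(match(smp, sample_ids), match(otu, otu_ids))] <- as.integer(as.numeric(cnt))
  otu_counts(counts, taxonomy = tx)
}

check_integer_cells <- function(m, otu_ids, path) {
  num <- suppressWarnings(apply(m, 2, as.numeric))
  bad <- which(!is_wholenumber(num) | num < 0, arr.ind = TRUE)
  if (length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    ur_stop(sprintf("%s: non-integer or negative count '%s' (OTU '%s', sample '%s')",
                    basename(path), m[bad[1, 1], bad[1, 2]],
                    otu_ids[bad[1, 1]], colnames(m)[bad[1, 2]]),
            "urostab_format_error")
  }
}

#' Write an OTU count table
#'
#' Round-trips bit-exactly through [read_otu_table()] in either dialect
#' (triplet files only carry nonzero cells, so all-zero rows/columns are the
#' one thing the sparse dialect cannot represent).
#'
#' @param x an `otu_counts` table.
#' @param path output path.
#' @param dialect `"tsv_dense"` or `"triplet_sparse"`.
#' @export
write_otu_table <- function(x, path, dialect = c("tsv_dense", "triplet_sparse")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "otu_counts"))
  if (dialect == "tsv_dense") {
    df <- data.frame(otu_id = colnames(x), t(unclass(x)), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(unclass(x) > 0, arr.ind = TRUE)
    df <- data.frame(otu_id = colnames(x)[nz[, 2]],
                     sample_id = rownames(x)[nz[, 1]],
                     count = x[nz])
    df <- df[order(df$otu_id, df$sample_id, method = "radix"), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a taxonomy file
#'
#' @param path two-column TSV with header `otu_id`, `lineage`.
#' @return Named character vector otu_id -> lineage.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% colnames(df)))
    ur_stop("taxonomy file must have columns 'otu_id' and 'lineage'",
            "urostab_format_error")
  stats::setNames(as.character(df$lineage), as.character(df$otu_id))
}
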
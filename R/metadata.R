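#' Read sample and subject metadata
#'
#' Parses a TSV with one row per sample and columns `subject_id`, `sample_id`,
#' `timepoint` (1 or 2), `method` (MSU or catheter), `sex` (F/M), `age`
#' (years), `cancer`, `stones` (logical-ish), and `interval_months`.
#' Categorical fields are matched case-insensitively.  Subject-level fields
#' must agree between a subject's two rows.
#'
#' Each subject must contribute exactly two samples, one per timepoint.  The
#' study design collects the second sample as mid-stream urine; a
#' second-timepoint sample recorded with another method raises a warning, not
#' an error, because external data need not follow that design.
#'
#' @param path TSV path.
#' @param col_map optional named character vector remapping canonical column
#'   names to the file's column names.
#' @return A list with elements `samples` (data.frame: sample_id, subject_id,
#'   timepoint, method) and `subjects` (data.frame: subject_id, sex, age,
#'   cancer, stones, interval_months).
#' @export
read_metadata <- function(path, col_map = NULL) {
  if (!file.exists(path))
    ur_stop(paste0("file not found: ", path), "urostab_io_error")
  # read everything as character: "F"/"T" sex codes must not become logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  canon <- c("subject_id", "sample_id", "timepoint", "method", "sex", "age",
             "cancer", "stones", "interval_months")
  need <- stats::setNames(canon, canon)
  if (!is.null(col_map)) need[names(col_map)] <- col_map
  missing_cols <- setdiff(unname(need), colnames(df))
  if (length(missing_cols) > 0)
    ur_stop(paste0("metadata missing columns: ", fmt_ids(missing_cols)),
            "urostab_format_error")
  g <- function(k) df[[need[k]]]

  samples <- data.frame(
    sample_id = as.character(g("sample_id")),
    subject_id = as.character(g("subject_id")),
    timepoint = as.integer(g("timepoint")),
    method = parse_level(g("method"), c(MSU = "msu", CATHETER = "catheter",
                                        CATHETER = "cath"), "method"),
    stringsAsFactors = FALSE)

  if (anyDuplicated(samples$sample_id))
    ur_stop(paste0("duplicate sample ids in metadata: ",
                   fmt_ids(unique(samples$sample_id[duplicated(samples$sample_id)]))),
            "urostab_validation_error")
  if (!all(samples$timepoint %in% c(1L, 2L)))
    ur_stop("timepoint must be 1 or 2", "urostab_validation_error")

  # pairing: exactly one sample per (subject, timepoint)
  tab <- table(samples$subject_id, samples$timepoint)
  full <- rownames(tab)[rowSums(tab) == 2 & apply(tab, 1, function(r) all(r == 1))]
  bad <- setdiff(unique(samples$subject_id), full)
  if (length(bad) > 0)
    ur_stop(paste0("subjects without exactly one sample per timepoint: ",
                   fmt_ids(bad)), "urostab_pairing_error")

  t2 <- samples$timepoint == 2L & samples$method != "MSU"
  if (any(t2))
    ur_warn(paste0("second-timepoint samples not collected as MSU: ",
                   fmt_ids(samples$sample_id[t2])), "urostab_design_warning")

  subj <- df[!duplicated(g("subject_id")), , drop = FALSE]
  subjects <- data.frame(
    subject_id = as.character(subj[[need["subject_id"]]]),
    sex = parse_level(subj[[need["sex"]]],
                      c(F = "f", F = "female", M = "m", M = "male"), "sex"),
    age = as.numeric(subj[[need["age"]]]),
    cancer = parse_logical(subj[[need["cancer"]]], "cancer"),
    stones = parse_logical(subj[[need["stones"]]], "stones"),
    interval_months = as.numeric(subj[[need["interval_months"]]]),
    stringsAsFactors = FALSE)

  # subject-level fields must be constant within subject
  for (field in c("sex", "age", "cancer", "stones", "interval_months")) {
    per <- tapply(df[[need[field]]], g("subject_id"),
                  function(v) length(unique(v)))
    if (any(per > 1))
      ur_stop(paste0("subject-level field '", field,
                     "' differs between a subject's rows: ",
                     fmt_ids(names(per)[per > 1])), "urostab_validation_error")
  }

  if (any(!is.finite(subjects$interval_months) | subjects$interval_months <= 0))
    ur_stop(paste0("interval_months must be > 0; offending subjects: ",
                   fmt_ids(subjects$subject_id[!(subjects$interval_months > 0)])),
            "urostab_validation_error")
  if (any(!is.finite(subjects$age) | subjects$age < 18))
    ur_stop(paste0("age must be >= 18; offending subjects: ",
                   fmt_ids(subjects$subject_id[!(subjects$age >= 18)])),
            "urostab_validation_error")

  samples <- samples[id_order(samples$sample_id), , drop = FALSE]
  subjects <- subjects[id_order(subjects$subject_id), , drop = FALSE]
  rownames(samples) <- rownames(subjects) <- NULL
  list(samples = samples, subjects = subjects)
}

parse_level <- function(x, map, field) {
  key <- tolower(trimws(as.character(x)))
  hit <- match(key, unname(map))
  if (anyNA(hit))
    ur_stop(paste0("unknown ", field, " level(s): ",
                   fmt_ids(unique(x[is.na(hit)]))), "urostab_validation_error")
  names(map)[hit]
}

parse_logical <- function(x, field) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[key %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out))
    ur_stop(paste0("cannot parse ", field, " as logical: ",
                   fmt_ids(unique(x[is.na(out)]))), "urostab_validation_error")
  out
}

#' Assemble a paired cohort
#'
#' Cross-checks the OTU table against the metadata and bundles them into the
#' structure every downstream stage consumes.  The sample id sets of table and
#' metadata must coincide exactly; `total_reads` is (re)computed from the
#' table, never trusted from a file.
#'
#' @param table an [otu_counts] table.
#' @param samples,subjects data frames as returned by [read_metadata()]
#'   (or the list returned by `read_metadata()` itself passed via `samples`).
#' @return An object of class `paired_cohort`: list with elements `table`,
#'   `samples` (with a `total_reads` column) and `subjects`.
#' @export
build_paired_cohort <- function(table, samples, subjects = NULL) {
  if (is.list(samples) && is.null(subjects) &&
      all(c("samples", "subjects") %in% names(samples))) {
    subjects <- samples$subjects
    samples <- samples$samples
  }
  stopifnot(inherits(table, "otu_counts"), is.data.frame(samples),
            is.data.frame(subjects))
  only_table <- setdiff(rownames(table), samples$sample_id)
  only_meta <- setdiff(samples$sample_id, rownames(table))
  if (length(only_table) + length(only_meta) > 0)
    ur_stop(paste0("sample ids do not reconcile; only in table: {",
                   fmt_ids(only_table), "}; only in metadata: {",
                   fmt_ids(only_meta), "}"), "urostab_reconciliation_error")
  ssubj <- setdiff(unique(samples$subject_id), subjects$subject_id)
  if (length(ssubj) > 0)
    ur_stop(paste0("samples reference unknown subjects: ", fmt_ids(ssubj)),
            "urostab_reconciliation_error")
  samples <- samples[id_order(samples$sample_id), , drop = FALSE]
  subjects <- subjects[subjects$subject_id %in% samples$subject_id, , drop = FALSE]
  subjects <- subjects[id_order(subjects$subject_id), , drop = FALSE]
  samples$total_reads <- unname(total_reads(table)[samples$sample_id])
  rownames(samples) <- rownames(subjects) <- NULL
  structure(list(table = table, samples = samples, subjects = subjects),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("Paired cohort: %d subjects, %d samples, %d OTUs\n",
              nrow(x$subjects), nrow(x$samples), ncol(x$table)))
  if (nrow(x$samples) > 0)
    cat(sprintf("reads/sample: median %s (range %s-%s)\n",
                format(stats::median(x$samples$total_reads)),
                format(min(x$samples$total_reads)),
                format(max(x$samples$total_reads))))
  if (nrow(x$subjects) > 0)
    cat(sprintf("interval: %.1f-%.1f months (median %.1f)\n",
                min(x$subjects$interval_months), max(x$subjects$interval_months),
                stats::median(x$subjects$interval_months)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `paired_cohort`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

# sample ids of a subject at timepoints 1 and 2 (internal)
subject_sample_ids <- function(cohort, subject_id) {
  s <- cohort$samples[cohort$samples$subject_id == subject_id, , drop = FALSE]
  c(t1 = s$sample_id[s$timepoint == 1L], t2 = s$sample_id[s$timepoint == 2L])
}
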
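#' Good's coverage of a sample
#'
#' Good's coverage estimates the fraction of reads belonging to OTUs observed
#' more than once: `C = 100 * (1 - F1/N)` on the percent scale, where `F1` is
#' the number of OTUs with count exactly 1 in the sample and `N` its total
#' reads.  It is used as a sequencing-depth adequacy gate.
#'
#' @param counts non-negative integer vector of one sample's OTU counts.
#' @return Coverage percent in `[0, 100]`.
#' @examples
#' goods_coverage(c(5, 3, 1, 1))  # 80
#' @export
goods_coverage <- function(counts) {
  if (any(!is_wholenumber(counts) | counts < 0))
    ur_stop("counts must be non-negative integers", "urostab_validation_error")
  n <- sum(counts)
  if (n == 0)
    ur_stop("coverage is undefined for an all-zero sample",
            "urostab_coverage_undefined_error")
  100 * (1 - sum(counts == 1) / n)
}

#' Exclude subject pairs with insufficient coverage
#'
#' Drops both samples of every subject for whom at least one sample has Good's
#' coverage strictly below `threshold` percent.  Coverage is computed on the
#' raw counts, before any OTU filtering (the gate runs first in the pipeline).
#'
#' @param cohort a `paired_cohort`.
#' @param threshold coverage percent below which a sample fails (default 85).
#' @return List with elements `cohort` (the filtered cohort) and `report`
#'   (class `coverage_report`): per-sample table of `total_reads`,
#'   `singletons` and `goods_coverage`, plus the excluded subjects and reasons.
#' @export
exclude_low_coverage_pairs <- function(cohort, threshold = 85) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (nrow(cohort$samples) == 0)
    ur_stop("cohort is empty", "urostab_empty_cohort_error")
  m <- unclass(cohort$table)
  per_sample <- data.frame(
    sample_id = rownames(m),
    subject_id = cohort$samples$subject_id[match(rownames(m), cohort$samples$sample_id)],
    total_reads = rowSums(m),
    singletons = rowSums(m == 1L),
    stringsAsFactors = FALSE)
  if (any(per_sample$total_reads == 0))
    ur_stop(paste0("all-zero samples have undefined coverage: ",
                   fmt_ids(per_sample$sample_id[per_sample$total_reads == 0])),
            "urostab_coverage_undefined_error")
  per_sample$goods_coverage <- 100 * (1 - per_sample$singletons / per_sample$total_reads)
  per_sample$pass <- per_sample$goods_coverage >= threshold

  fail_subj <- unique(per_sample$subject_id[!per_sample$pass])
  excluded <- per_sample[per_sample$subject_id %in% fail_subj & !per_sample$pass,
                         c("subject_id", "sample_id", "goods_coverage")]
  excluded$reason <- sprintf("Good's coverage %.2f%% < %g%%",
                             excluded$goods_coverage, threshold)
  keep_subj <- setdiff(cohort$subjects$subject_id, fail_subj)
  if (length(keep_subj) == 0)
    ur_stop("all subjects excluded by the coverage gate",
            "urostab_empty_cohort_error")

  keep_samples <- cohort$samples$sample_id[cohort$samples$subject_id %in% keep_subj]
  out <- cohort
  out$table <- cohort$table[rownames(cohort$table) %in% keep_samples, , drop = FALSE]
  out$samples <- cohort$samples[cohort$samples$subject_id %in% keep_subj, , drop = FALSE]
  out$subjects <- cohort$subjects[cohort$subjects$subject_id %in% keep_subj, , drop = FALSE]
  rownames(out$samples) <- rownames(out$subjects) <- NULL

  report <- structure(list(per_sample = per_sample, excluded = excluded,
                           threshold = threshold,
                           n_excluded_subjects = length(fail_subj),
                           n_retained_subjects = length(keep_subj)),
                      class = "coverage_report")
  list(cohort = out, report = report)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Good's coverage gate at %g%%: %d subjects excluded, %d retained\n",
              x$threshold, x$n_excluded_subjects, x$n_retained_subjects))
  if (nrow(x$excluded) > 0) {
    cat("excluded:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Remove global singleton OTUs
#'
#' A global singleton is an OTU whose summed count across the entire dataset
#' equals exactly 1; such OTUs are likely sequencing artifacts and are removed
#' before occurrence/abundance analyses.  The sample set is unchanged.
#'
#' @param x an `otu_counts` table or a `paired_cohort` (whose table is
#'   filtered in place).
#' @return Object of the same class with global-singleton OTUs dropped.
#' @export
remove_global_singletons <- function(x) UseMethod("remove_global_singletons")

#' @export
remove_global_singletons.otu_counts <- function(x) {
  keep <- colSums(x) != 1L
  x[, keep, drop = FALSE]
}

#' @export
remove_global_singletons.paired_cohort <- function(x) {
  x$table <- remove_global_singletons(x$table)
  x
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total so per-sample values sum to 1.
#' Proportions are kept on the `[0, 1]` scale internally; reporting layers
#' multiply by 100.
#'
#' @param x an `otu_counts` table (or a `paired_cohort`, whose table is used).
#' @return A numeric matrix (samples x OTUs) of class `rel_abundance` whose
#'   rows each sum to 1; taxonomy is carried over.
#' @export
to_relative_abundance <- function(x) {
  if (inherits(x, "paired_cohort")) x <- x$table
  stopifnot(inherits(x, "otu_counts"))
  tot <- rowSums(x)
  if (any(tot == 0))
    ur_stop(paste0("cannot normalize zero-read sample(s): ",
                   fmt_ids(rownames(x)[tot == 0])), "urostab_normalization_error")
  out <- unclass(x) / tot
  structure(out, taxonomy = attr(x, "taxonomy"),
            class = c("rel_abundance", "matrix", "array"))
}

#' Run the standard QC sequence on a cohort
#'
#' Fixed order: coverage gate on raw counts, then global-singleton removal.
#' Normalization is performed by the consumers that need proportions.
#'
#' @param cohort a `paired_cohort`.
#' @param coverage_threshold Good's coverage gate in percent (default 85).
#' @param drop_global_singletons logical (default TRUE).
#' @return List with `cohort` (filtered) and `report` (the coverage report).
#' @export
qc_cohort <- function(cohort, coverage_threshold = 85,
                      drop_global_singletons = TRUE) {
  gated <- exclude_low_coverage_pairs(cohort, threshold = coverage_threshold)
  out <- gated$cohort
  if (drop_global_singletons) out <- remove_global_singletons(out)
  list(cohort = out, report = gated$report)
}
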
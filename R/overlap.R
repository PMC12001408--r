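#' Overlap statistics for one sample pair
#'
#' Given the relative-abundance vectors of a subject's two samples over a
#' common OTU index, computes the number of OTUs detected (nonzero) at each
#' timepoint, the number detected at both ("overlapping" OTUs), the overlap
#' fraction, and the shared relative abundance: the summed relative abundance
#' of the overlapping OTUs in each sample and the average of the two
#' (`(abundance_1 + abundance_2) / 2`), the study's persistence statistic.
#'
#' @param t1,t2 named relative-abundance vectors over the same OTU index
#'   (each summing to 1).
#' @param frac_denominator denominator convention for the overlap fraction:
#'   `"mean"` (default; shared count over the mean of the two per-sample
#'   richness values), `"union"` or `"min"`.
#' @return One-row data.frame with columns `n_otus_t1`, `n_otus_t2`,
#'   `n_shared`, `frac_shared`, `shared_abund_t1`, `shared_abund_t2`,
#'   `shared_abund_mean`.
#' @examples
#' t1 <- c(o1 = 0.5, o2 = 0.5, o3 = 0)
#' t2 <- c(o1 = 0.3, o2 = 0, o3 = 0.7)
#' subject_overlap(t1, t2)  # n_shared 1, shared_abund_mean 0.4
#' @export
subject_overlap <- function(t1, t2, frac_denominator = c("mean", "union", "min")) {
  frac_denominator <- match.arg(frac_denominator)
  if (length(t1) != length(t2) ||
      (!is.null(names(t1)) && !is.null(names(t2)) && !identical(names(t1), names(t2))))
    ur_stop("the two abundance vectors must share one OTU index",
            "urostab_alignment_error")
  p1 <- t1 > 0
  p2 <- t2 > 0
  both <- p1 & p2
  n1 <- sum(p1); n2 <- sum(p2); ns <- sum(both)
  denom <- switch(frac_denominator,
                  mean = (n1 + n2) / 2,
                  union = sum(p1 | p2),
                  min = min(n1, n2))
  a1 <- sum(t1[both]); a2 <- sum(t2[both])
  data.frame(n_otus_t1 = n1, n_otus_t2 = n2, n_shared = ns,
             frac_shared = if (denom > 0) ns / denom else NA_real_,
             shared_abund_t1 = a1, shared_abund_t2 = a2,
             shared_abund_mean = (a1 + a2) / 2)
}

#' Cohort-wide overlap statistics
#'
#' Normalizes the cohort's (QC'd, singleton-filtered) count table and computes
#' one [subject_overlap()] row per subject, with subject covariates attached,
#' plus aggregate summaries overall and stratified by sex, cancer status and
#' collection-method combination (MSU/MSU when the first sample was voided,
#' CATH/MSU when it was catheterized).
#'
#' @param cohort a `paired_cohort`.
#' @param frac_denominator see [subject_overlap()].
#' @return Object of class `overlap_summary`: list with `summary` (data.frame,
#'   one row per subject, including `method_pair`, `sex`, `age`, `cancer`,
#'   `stones`, `interval_months`) and `aggregates` (named list of data.frames
#'   of mean/sd/median/IQR per statistic).
#' @export
cohort_overlap <- function(cohort, frac_denominator = c("mean", "union", "min")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  frac_denominator <- match.arg(frac_denominator)
  if (nrow(cohort$subjects) == 0)
    ur_stop("cohort is empty", "urostab_empty_cohort_error")
  rel <- to_relative_abundance(cohort$table)

  rows <- lapply(cohort$subjects$subject_id, function(sj) {
    ids <- subject_sample_ids(cohort, sj)
    row <- subject_overlap(rel[ids[["t1"]], ], rel[ids[["t2"]], ],
                           frac_denominator = frac_denominator)
    m1 <- cohort$samples$method[cohort$samples$sample_id == ids[["t1"]]]
    cbind(data.frame(subject_id = sj, stringsAsFactors = FALSE), row,
          data.frame(method_pair = if (m1 == "MSU") "MSU/MSU" else "CATH/MSU",
                     stringsAsFactors = FALSE))
  })
  summary_df <- do.call(rbind, rows)
  summary_df <- merge(summary_df, cohort$subjects, by = "subject_id", sort = FALSE)
  summary_df <- summary_df[id_order(summary_df$subject_id), , drop = FALSE]
  rownames(summary_df) <- NULL

  stats_of <- function(v) {
    v <- v[is.finite(v)]
    data.frame(mean = mean(v), sd = stats::sd(v), median = stats::median(v),
               iqr = stats::IQR(v), n = length(v))
  }
  fields <- c("n_otus_t1", "n_otus_t2", "n_shared", "frac_shared",
              "shared_abund_t1", "shared_abund_t2", "shared_abund_mean")
  agg_for <- function(df) {
    out <- do.call(rbind, lapply(fields, function(f) stats_of(df[[f]])))
    out <- cbind(data.frame(statistic = fields, stringsAsFactors = FALSE), out)
    # per-sample richness pools both timepoints (as reported per urine sample)
    rich <- stats_of(c(df$n_otus_t1, df$n_otus_t2))
    rbind(cbind(data.frame(statistic = "n_otus_per_sample"), rich), out)
  }
  strata <- list(overall = summary_df)
  for (v in c("sex", "cancer", "method_pair"))
    for (lev in unique(summary_df[[v]]))
      strata[[paste0(v, "=", lev)]] <- summary_df[summary_df[[v]] == lev, , drop = FALSE]
  aggregates <- lapply(strata, agg_for)

  structure(list(summary = summary_df, aggregates = aggregates,
                 frac_denominator = frac_denominator),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, digits = 3, ...) {
  ov <- x$aggregates$overall
  g <- function(stat, col) ov[ov$statistic == stat, col]
  cat(sprintf("Overlap summary for %d subjects\n", nrow(x$summary)))
  cat(sprintf("  OTUs per sample:      %.0f +/- %.0f\n",
              g("n_otus_per_sample", "mean"), g("n_otus_per_sample", "sd")))
  cat(sprintf("  overlapping OTUs:     %.0f +/- %.0f (%.0f%% +/- %.0f%%)\n",
              g("n_shared", "mean"), g("n_shared", "sd"),
              100 * g("frac_shared", "mean"), 100 * g("frac_shared", "sd")))
  cat(sprintf("  shared rel. abund.:   %.1f%% +/- %.1f%% (median %.1f%%)\n",
              100 * g("shared_abund_mean", "mean"),
              100 * g("shared_abund_mean", "sd"),
              100 * g("shared_abund_mean", "median")))
  invisible(x)
}

#' Prevalence of persistently detected OTUs by sex
#'
#' An OTU counts as present for a subject only when detected in both of the
#' subject's samples.  Presence is tallied per sex; OTUs reaching at least
#' `min_prevalence` in either sex are returned, sorted by male then female
#' prevalence, descending.
#'
#' @param cohort a `paired_cohort` (normalized internally).
#' @param min_prevalence prevalence fraction threshold (default 0.5).
#' @return data.frame with `otu_id`, `label` (taxonomy lineage when
#'   available), `n_present_males`, `pct_males`, `n_present_females`,
#'   `pct_females`.
#' @export
prevalence_table <- function(cohort, min_prevalence = 0.5) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(cohort$subjects$sex) || anyNA(cohort$subjects$sex))
    ur_stop("prevalence_table requires sex metadata", "urostab_validation_error")
  m <- unclass(cohort$table) > 0
  pres <- sapply(cohort$subjects$subject_id, function(sj) {
    ids <- subject_sample_ids(cohort, sj)
    m[ids[["t1"]], ] & m[ids[["t2"]], ]
  })                                     # OTUs x subjects
  sex <- cohort$subjects$sex
  n_m <- sum(sex == "M"); n_f <- sum(sex == "F")
  cnt_m <- if (n_m > 0) rowSums(pres[, sex == "M", drop = FALSE]) else 0L
  cnt_f <- if (n_f > 0) rowSums(pres[, sex == "F", drop = FALSE]) else 0L
  tx <- attr(cohort$table, "taxonomy")
  out <- data.frame(
    otu_id = colnames(cohort$table),
    label = if (is.null(tx)) colnames(cohort$table)
            else ifelse(is.na(tx[colnames(cohort$table)]),
                        colnames(cohort$table), tx[colnames(cohort$table)]),
    n_present_males = as.integer(cnt_m),
    pct_males = if (n_m > 0) 100 * cnt_m / n_m else NA_real_,
    n_present_females = as.integer(cnt_f),
    pct_females = if (n_f > 0) 100 * cnt_f / n_f else NA_real_,
    stringsAsFactors = FALSE)
  keep <- (!is.na(out$pct_males) & out$pct_males >= 100 * min_prevalence) |
          (!is.na(out$pct_females) & out$pct_females >= 100 * min_prevalence)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$pct_males, -out$pct_females, out$otu_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant-discordant OTUs of a pair
#'
#' Flags OTUs with relative abundance strictly above `dominance_threshold` in
#' one sample of a pair while completely absent (zero) in the other — the
#' diagnostic pattern for pairs whose communities flipped between collections.
#'
#' @param t1,t2 named relative-abundance vectors over the same OTU index.
#' @param dominance_threshold abundance fraction (default 0.5).
#' @return Character vector of OTU ids (possibly empty).
#' @export
dominant_discordant <- function(t1, t2, dominance_threshold = 0.5) {
  if (length(t1) != length(t2) ||
      (!is.null(names(t1)) && !is.null(names(t2)) && !identical(names(t1), names(t2))))
    ur_stop("the two abundance vectors must share one OTU index",
            "urostab_alignment_error")
  hit <- (t1 > dominance_threshold & t2 == 0) | (t2 > dominance_threshold & t1 == 0)
  ids <- names(t1) %||% as.character(seq_along(t1))
  ids[hit]
}
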
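# fixtures built in code: tiny hand-auditable cohorts and file writers

make_counts <- function(m, sample_ids = NULL, otu_ids = NULL, taxonomy = NULL) {
  if (!is.null(sample_ids)) rownames(m) <- sample_ids
  if (!is.null(otu_ids)) colnames(m) <- otu_ids
  otu_counts(m, taxonomy = taxonomy)
}

# random sparse count table for property tests
random_counts <- function(n_samples = 6, n_otus = 30, lambda = 2,
                          zero_frac = 0.6) {
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  m[stats::runif(length(m)) < zero_frac] <- 0L
  m[1, 1] <- m[1, 1] + 1L  # guarantee no all-zero first sample
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("o%03d", seq_len(n_otus)))
  m
}

write_meta_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

meta_df <- function(n_subjects = 3, method1 = "MSU", interval = NULL) {
  sj <- sprintf("sub%d", seq_len(n_subjects))
  interval <- interval %||% seq(6, by = 6, length.out = n_subjects)
  data.frame(
    subject_id = rep(sj, each = 2),
    sample_id = paste0(rep(sj, each = 2), "_t", 1:2),
    timepoint = rep(1:2, n_subjects),
    method = rep(c(method1, "MSU"), n_subjects),
    sex = rep(rep(c("F", "M"), length.out = n_subjects), each = 2),
    age = rep(seq(40, by = 5, length.out = n_subjects), each = 2),
    cancer = rep(rep(c(TRUE, FALSE), length.out = n_subjects), each = 2),
    stones = rep(FALSE, 2 * n_subjects),
    interval_months = rep(interval, each = 2),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# paired cohort with hand-set counts: one matrix row per metadata row
tiny_cohort <- function(counts = NULL, n_subjects = 3, method1 = "MSU",
                        interval = NULL, taxonomy = NULL) {
  md <- meta_df(n_subjects, method1 = method1, interval = interval)
  if (is.null(counts)) {
    set.seed(99)
    counts <- matrix(stats::rpois(2 * n_subjects * 8, 5) + 1L,
                     nrow = 2 * n_subjects, ncol = 8)
  }
  rownames(counts) <- md$sample_id
  colnames(counts) <- colnames(counts) %||% sprintf("o%d", seq_len(ncol(counts)))
  tab <- otu_counts(counts, taxonomy = taxonomy)
  meta <- list(samples = md[c("sample_id", "subject_id", "timepoint", "method")],
               subjects = unique(md[c("subject_id", "sex", "age", "cancer",
                                      "stones", "interval_months")]))
  build_paired_cohort(tab, meta$samples, meta$subjects)
}
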
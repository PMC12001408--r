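#' Configuration for the synthetic paired-cohort generator
#'
#' Defaults emulate the study cohort: 63 subjects sampled twice 3-40 months
#' apart, sequencing depths around 11,524 +/- 8,669 reads, per-subject taxon
#' pools around 152 +/- 128 OTUs, a persistent core covering ~27% of taxa,
#' and a shared-abundance level that starts near 99.78% at a zero interval
#' and declines by 0.66 percentage points per month with +/- 15% subject
#' noise, truncated to the physical [0, 100]% range.
#'
#' @param n_subjects number of subjects (default 63).
#' @param global_pool_size size of the OTU universe (default 2000).
#' @param subject_pool_mean,subject_pool_sd mean/sd of the per-subject taxon
#'   pool size; drawn log-normally, truncated to `[5, global_pool_size/2]`.
#' @param abundance_shape Dirichlet concentration of compositions
#'   (default 0.3, long-tailed).
#' @param persistence_prob probability that a timepoint-1 taxon persists to
#'   timepoint 2 (default 0.27).
#' @param shared_abund_intercept_pct,shared_abund_slope_pct_per_month,shared_abund_noise_sd_pct
#'   linear drift of the persistent community's mixture weight, percent scale
#'   (defaults 99.78, -0.66, 15).
#' @param interval_min,interval_max uniform collection-interval range in
#'   months (defaults 3, 40).
#' @param depth_mean,depth_sd log-normal sequencing-depth parameters
#'   (defaults 11524, 8669).
#' @param depth_min lower truncation of depths (default 1000, which
#'   guarantees default-depth rarefaction is feasible; lower it to exercise
#'   the exclusion rule).
#' @param age_mean,age_sd,age_min truncated-normal age model
#'   (defaults 61.1, 14.8, 18).
#' @param p_male,p_cancer,p_stones,p_catheter_t1 covariate probabilities
#'   (defaults 43/63, 28/63, 22/63, 26/63).
#' @param seed default seed used by [generate_cohort()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 63,
                             global_pool_size = 2000,
                             subject_pool_mean = 152,
                             subject_pool_sd = 128,
                             abundance_shape = 0.3,
                             persistence_prob = 0.27,
                             shared_abund_intercept_pct = 99.78,
                             shared_abund_slope_pct_per_month = -0.66,
                             shared_abund_noise_sd_pct = 15,
                             interval_min = 3,
                             interval_max = 40,
                             depth_mean = 11524,
                             depth_sd = 8669,
                             depth_min = 1000,
                             age_mean = 61.1,
                             age_sd = 14.8,
                             age_min = 18,
                             p_male = 43 / 63,
                             p_cancer = 28 / 63,
                             p_stones = 22 / 63,
                             p_catheter_t1 = 26 / 63,
                             seed = 1) {
  cfg <- as.list(environment())
  probs <- c(persistence_prob, p_male, p_cancer, p_stones, p_catheter_t1)
  if (any(probs < 0 | probs > 1))
    ur_stop("probabilities must lie in [0, 1]", "urostab_config_error")
  if (n_subjects < 1 || global_pool_size < 20 || abundance_shape <= 0 ||
      interval_min <= 0 || interval_max < interval_min ||
      depth_min < 1 || subject_pool_mean < 5)
    ur_stop("infeasible synthetic configuration", "urostab_config_error")
  if (subject_pool_mean > global_pool_size / 2)
    ur_stop("global pool cannot supply the novel taxa required at timepoint 2",
            "urostab_config_error")
  structure(cfg, class = "synthetic_config")
}

# log-normal meanlog/sdlog from a target mean and sd
lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

rtrunc <- function(n, rfun, lo = -Inf, hi = Inf, max_tries = 10000) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n && tries < max_tries) {
    x <- rfun(n)
    out <- c(out, x[x >= lo & x <= hi])
    tries <- tries + 1
  }
  out[seq_len(n)]
}

#' Generate a synthetic paired cohort with known ground truth
#'
#' Each subject receives a taxon pool drawn from a global OTU universe and a
#' persistent subset (Bernoulli `persistence_prob` per pool taxon).  The
#' persistent taxa carry a mixture weight
#' `w = clamp((intercept + slope * interval + noise)/100, 0, 1)` of the
#' community at both collections — `w` is the fraction of community mass that
#' persists across the interval — while the remaining `1 - w` goes to
#' subject-specific transient taxa at timepoint 1 and to novel taxa at
#' timepoint 2.  Counts are multinomial draws of the per-sample compositions
#' at log-normally distributed sequencing depths.  The expected shared
#' relative abundance at each timepoint therefore equals `w` up to detection
#' loss, which makes the configured drift slope recoverable by the pipeline's
#' own decay model.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`); the result is a
#'   deterministic function of `(config, seed)`.
#' @return List with `cohort` (a ready [build_paired_cohort()] object) and
#'   `truth` (class `synthetic_truth`): per-subject data.frame of interval,
#'   pool size, persistent-set size, the realized mixture weight `w`, and
#'   whether the clamp fired; plus the persistent OTU sets and the resolved
#'   configuration.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n <- config$n_subjects
  pool <- config$global_pool_size
  otu_ids <- sprintf("OTU%04d", seq_len(pool))
  subject_ids <- sprintf("sub%03d", seq_len(n))
  pp <- lnorm_pars(config$subject_pool_mean, config$subject_pool_sd)
  dp <- lnorm_pars(config$depth_mean, config$depth_sd)

  counts <- matrix(0L, nrow = 2 * n, ncol = pool,
                   dimnames = list(rep("", 2 * n), otu_ids))
  samples <- vector("list", n)
  subjects <- vector("list", n)
  truth_rows <- vector("list", n)
  persistent_sets <- stats::setNames(vector("list", n), subject_ids)

  for (i in seq_len(n)) {
    sj <- subject_ids[i]
    interval <- stats::runif(1, config$interval_min, config$interval_max)
    age <- rtrunc(1, function(k) stats::rnorm(k, config$age_mean, config$age_sd),
                  lo = config$age_min)
    sex <- if (stats::runif(1) < config$p_male) "M" else "F"
    cancer <- stats::runif(1) < config$p_cancer
    stones <- stats::runif(1) < config$p_stones
    method1 <- if (stats::runif(1) < config$p_catheter_t1) "CATHETER" else "MSU"

    s_i <- round(rtrunc(1, function(k) stats::rlnorm(k, pp["meanlog"], pp["sdlog"]),
                        lo = 5, hi = floor(pool / 2)))
    n_pers <- stats::rbinom(1, s_i, config$persistence_prob)
    n_side <- s_i - n_pers                       # transient (t1) = novel (t2) count
    drawn <- sample.int(pool, n_pers + 2 * n_side)
    pers <- drawn[seq_len(n_pers)]
    trans <- drawn[n_pers + seq_len(n_side)]
    novel <- drawn[n_pers + n_side + seq_len(n_side)]

    w_lin <- (config$shared_abund_intercept_pct +
              config$shared_abund_slope_pct_per_month * interval +
              stats::rnorm(1, 0, config$shared_abund_noise_sd_pct)) / 100
    w <- min(max(w_lin, 0), 1)
    clamped <- w != w_lin
    if (n_pers == 0) w_real <- 0
    else if (n_side == 0) w_real <- 1
    else w_real <- w

    dir_w <- function(k) {
      if (k == 0) return(numeric(0))
      g <- stats::rgamma(k, shape = config$abundance_shape)
      if (sum(g) == 0) g <- rep(1, k)
      g / sum(g)
    }
    p_pers <- dir_w(n_pers)
    p_t1 <- c(w_real * p_pers, (1 - w_real) * dir_w(n_side))
    p_t2 <- c(w_real * p_pers, (1 - w_real) * dir_w(n_side))
    sup_t1 <- c(pers, trans)
    sup_t2 <- c(pers, novel)

    d1 <- round(rtrunc(1, function(k) stats::rlnorm(k, dp["meanlog"], dp["sdlog"]),
                       lo = config$depth_min))
    d2 <- round(rtrunc(1, function(k) stats::rlnorm(k, dp["meanlog"], dp["sdlog"]),
                       lo = config$depth_min))
    counts[2 * i - 1, sup_t1] <- as.integer(stats::rmultinom(1, d1, p_t1))
    counts[2 * i, sup_t2] <- as.integer(stats::rmultinom(1, d2, p_t2))
    rownames(counts)[c(2 * i - 1, 2 * i)] <- paste0(sj, "_t", 1:2)

    samples[[i]] <- data.frame(
      sample_id = paste0(sj, "_t", 1:2), subject_id = sj, timepoint = 1:2,
      method = c(method1, "MSU"), stringsAsFactors = FALSE)
    subjects[[i]] <- data.frame(
      subject_id = sj, sex = sex, age = age, cancer = cancer, stones = stones,
      interval_months = interval, stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      subject_id = sj, interval_months = interval, n_pool = s_i,
      n_persistent = n_pers, w = w_real, w_unclamped_pct = 100 * w_lin,
      clamped = clamped, stringsAsFactors = FALSE)
    persistent_sets[[sj]] <- otu_ids[pers]
  }

  table <- otu_counts(counts)
  cohort <- build_paired_cohort(table, do.call(rbind, samples),
                                do.call(rbind, subjects))
  truth <- structure(
    list(subjects = do.call(rbind, truth_rows),
         persistent_sets = persistent_sets,
         config = config, seed = seed,
         n_clamped = sum(vapply(truth_rows, function(r) r$clamped, logical(1)))),
    class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth for %d subjects (seed %s)\n",
              nrow(x$subjects), format(x$seed)))
  cat(sprintf("configured drift: %.2f %+.2f %%/month, noise sd %.1f%%; clamp fired for %d subjects\n",
              x$config$shared_abund_intercept_pct,
              x$config$shared_abund_slope_pct_per_month,
              x$config$shared_abund_noise_sd_pct, x$n_clamped))
  invisible(x)
}

#' Inject artificial global singletons
#'
#' Adds `Poisson(rate * n_samples)` new OTUs, each with a single read placed
#' in one random sample — material for [remove_global_singletons()] to remove.
#'
#' @param table an `otu_counts` table.
#' @param rate expected singletons per sample (>= 0).
#' @param seed optional seed.
#' @return The augmented table, with attribute `n_injected`.
#' @export
inject_singletons <- function(table, rate, seed = NULL) {
  stopifnot(inherits(table, "otu_counts"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- stats::rpois(1, rate * nrow(table))
  if (k == 0) {
    attr(table, "n_injected") <- 0L
    return(table)
  }
  new_ids <- sprintf("SING%05d", seq_len(k))
  stopifnot(!any(new_ids %in% colnames(table)))
  add <- matrix(0L, nrow(table), k, dimnames = list(rownames(table), new_ids))
  add[cbind(sample.int(nrow(table), k, replace = TRUE), seq_len(k))] <- 1L
  out <- otu_counts(cbind(unclass(table), add), taxonomy = attr(table, "taxonomy"))
  attr(out, "n_injected") <- k
  out
}

#' Join ground truth to pipeline estimates
#'
#' Flat per-subject table of the generator's truth next to the pipeline's
#' overlap estimates, for parameter-recovery inspection.
#'
#' @param truth a `synthetic_truth`.
#' @param overlap optional `overlap_summary` computed on the generated cohort.
#' @param path optional TSV output path (header always written, even for an
#'   empty truth).
#' @return data.frame (invisibly when `path` is given).
#' @export
truth_report <- function(truth, overlap = NULL, path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- truth$subjects
  if (!is.null(overlap)) {
    ov <- if (inherits(overlap, "overlap_summary")) overlap$summary else overlap
    df <- merge(df, ov[, c("subject_id", "n_shared", "frac_shared",
                           "shared_abund_t1", "shared_abund_t2",
                           "shared_abund_mean")],
                by = "subject_id", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
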
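#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1*(F1 - 1) / (2*(F2 + 1))`, where `F1` and `F2` are the numbers
#' of OTUs observed exactly once and exactly twice.  The bias-corrected form
#' stays finite when no doubletons are present; the classic form
#' `S_obs + F1^2/(2*F2)` is available for sensitivity runs.
#'
#' @param counts non-negative integer vector of one sample's OTU counts.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return Chao1 estimate (>= observed richness).
#' @examples
#' chao1(c(1, 1, 2, 3))  # 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(!is_wholenumber(counts) | counts < 0))
    ur_stop("counts must be non-negative integers", "urostab_validation_error")
  if (length(counts) == 0 || sum(counts) == 0) {
    ur_warn("Chao1 of an empty sample is 0", "urostab_degenerate_warning")
    return(0)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon diversity index
#'
#' Entropy of the relative-abundance vector, `H = -sum(p_i * log(p_i))` over
#' nonzero proportions.  Natural log by default.
#'
#' @param x non-negative counts or proportions, sum > 0.
#' @param base logarithm base (default `exp(1)`, nats).
#' @return Shannon index, `0 <= H <= log(S_obs, base)`.
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0) || any(!is.finite(x)))
    ur_stop("abundances must be finite and non-negative", "urostab_validation_error")
  tot <- sum(x)
  if (tot == 0)
    ur_stop("Shannon index is undefined for an all-zero sample",
            "urostab_degenerate_error")
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Rarefy one sample to a fixed depth
#'
#' Draws `depth` reads without replacement from the sample's reads
#' (multivariate hypergeometric), using the current RNG state.
#'
#' @param counts non-negative integer vector, `sum(counts) >= depth`.
#' @param depth number of reads to retain.
#' @return Integer vector of the same length summing to `depth`.
#' @export
rarefy_once <- function(counts, depth) {
  n <- sum(counts)
  if (depth < 1 || !is_wholenumber(depth))
    ur_stop("depth must be a positive integer", "urostab_validation_error")
  if (n < depth)
    ur_stop(sprintf("sample has %d reads, fewer than depth %d", n, depth),
            "urostab_insufficient_depth_error")
  if (n == depth) return(as.integer(counts))
  # index sampled reads into OTU bins via the cumulative count vector
  idx <- sample.int(n, depth)
  bins <- findInterval(idx - 1L, cumsum(counts)) + 1L
  out <- tabulate(bins, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Iterated-rarefaction alpha diversity
#'
#' Applies the paired-design exclusion rule (a subject is dropped when either
#' of its samples has fewer reads than `depth`), then rarefies every retained
#' sample `iterations` times and averages Chao1, Shannon and observed richness
#' over the iterations.  Each sample gets its own RNG stream derived from
#' `(seed, sample_id)`, so results do not depend on cohort ordering.
#'
#' @param cohort a `paired_cohort` (post-QC).
#' @param depth rarefaction depth in reads (default 1000).
#' @param iterations number of random subsamples per sample (default 1000).
#' @param seed integer seed.
#' @param base log base for Shannon.
#' @return Object of class `alpha_result`: data.frame with one row per
#'   retained sample (`sample_id`, `subject_id`, `timepoint`, `chao1_mean`,
#'   `chao1_sd`, `shannon_mean`, `shannon_sd`, `sobs_mean`) plus attributes
#'   `excluded_subjects`, `depth`, `iterations`, `seed`.
#' @export
iterated_alpha <- function(cohort, depth = 1000, iterations = 1000, seed = 1,
                           base = exp(1)) {
  stopifnot(inherits(cohort, "paired_cohort"))
  totals <- rowSums(cohort$table)
  shallow <- names(totals)[totals < depth]
  drop_subj <- unique(cohort$samples$subject_id[cohort$samples$sample_id %in% shallow])
  keep <- cohort$samples[!cohort$samples$subject_id %in% drop_subj, , drop = FALSE]
  if (nrow(keep) == 0)
    ur_stop("no subject meets the rarefaction depth", "urostab_empty_result_error")

  m <- unclass(cohort$table)
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    sid <- keep$sample_id[i]
    x <- m[sid, ]
    x <- x[x > 0]
    old <- get0(".Random.seed", globalenv())
    set.seed(stream_seed(seed, sid))
    ch <- sh <- so <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r <- rarefy_once(x, depth)
      ch[it] <- chao1(r)
      sh[it] <- shannon(r, base = base)
      so[it] <- sum(r > 0)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    data.frame(sample_id = sid, subject_id = keep$subject_id[i],
               timepoint = keep$timepoint[i],
               chao1_mean = mean(ch), chao1_sd = stats::sd(ch),
               shannon_mean = mean(sh), shannon_sd = stats::sd(sh),
               sobs_mean = mean(so), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, excluded_subjects = drop_subj, depth = depth,
            iterations = iterations, seed = seed,
            class = c("alpha_result", "data.frame"))
}

#' Expected rarefied richness (closed form)
#'
#' Expected number of OTUs detected when `depth` reads are drawn without
#' replacement: `sum_i (1 - choose(N - n_i, d) / choose(N, d))`.  Used as the
#' analytic reference for the rarefaction machinery.
#'
#' @param counts non-negative integer vector.
#' @param depth subsample size.
#' @return Expected richness (numeric).
#' @export
expected_rarefied_richness <- function(counts, depth) {
  n <- sum(counts)
  if (n < depth)
    ur_stop("depth exceeds sample total", "urostab_insufficient_depth_error")
  x <- counts[counts > 0]
  # lchoose for numerical stability at large N
  sum(1 - exp(lchoose(n - x, depth) - lchoose(n, depth)))
}
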
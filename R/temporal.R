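#' Squared Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return List of class `urostab_test`: `r`, `r_squared`, `p`, `n`,
#'   `statistic` (the t statistic on `n - 2` df).
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    ur_stop("need two equal-length vectors with n >= 3", "urostab_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ur_stop("correlation undefined for a constant vector",
            "urostab_degenerate_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("Pearson correlation", unname(ct$statistic), ct$p.value,
              length(x), sprintf("t on %d df", length(x) - 2L),
              r = unname(ct$estimate), r_squared = unname(ct$estimate)^2)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (the classical Wilcoxon convention).  The
#' exact null distribution (sign enumeration) is used when at most
#' `exact_max` nonzero differences remain and their absolute values are
#' untied; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for the exact null (default 25).
#' @param force `"auto"` (default), `"exact"` or `"approx"`, mostly for
#'   validation against enumeration.
#' @return `urostab_test` list: `statistic` (V, sum of positive ranks), `p`
#'   (two-sided), `n` (nonzero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25, force = c("auto", "exact", "approx")) {
  force <- match.arg(force)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    ur_stop("all paired differences are zero", "urostab_degenerate_error")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- switch(force, auto = n <= exact_max && !ties,
                  exact = TRUE, approx = FALSE)
  if (exact && ties)
    ur_stop("exact signed-rank null requires untied |differences|",
            "urostab_validation_error")
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("Wilcoxon signed-rank", unname(wt$statistic), wt$p.value, n,
              if (exact) "exact sign enumeration"
              else "normal approximation, tie/continuity corrected")
}

#' Two-group and k-group location tests
#'
#' Dispatches to the rank-sum (Mann-Whitney) test, Student/Welch t-test, or
#' Kruskal-Wallis test.  Mid-ranks are used for ties; the rank-sum test is
#' exact for small untied samples.
#'
#' @param values numeric vector of observations.
#' @param group grouping vector (coerced to factor).
#' @param test `"wilcoxon_rank_sum"`, `"student_t"` or `"kruskal_wallis"`.
#' @param welch for `student_t`, use the Welch correction (default TRUE).
#' @return `urostab_test` list: `statistic`, `p`, `n` (per-group sizes),
#'   `method`.
#' @export
group_test <- function(values, group,
                       test = c("wilcoxon_rank_sum", "student_t", "kruskal_wallis"),
                       welch = TRUE) {
  test <- match.arg(test)
  group <- factor(group)
  sizes <- table(group)
  if (length(sizes) < 2 || any(sizes < 2))
    ur_stop("need at least two groups with at least two observations each",
            "urostab_validation_error")
  if (test != "kruskal_wallis" && length(sizes) != 2)
    ur_stop(paste0(test, " requires exactly two groups"), "urostab_validation_error")
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  out <- switch(test,
    wilcoxon_rank_sum = {
      wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
      test_result("Wilcoxon rank-sum", unname(wt$statistic), wt$p.value,
                  as.integer(sizes),
                  if (grepl("exact", wt$method, ignore.case = TRUE) ||
                      (length(x) < 50 && length(y) < 50 &&
                       !anyDuplicated(c(x, y)))) "exact" else "normal approximation")
    },
    student_t = {
      tt <- stats::t.test(x, y, var.equal = !welch)
      test_result(tt$method, unname(tt$statistic), tt$p.value, as.integer(sizes),
                  sprintf("t on %.2f df", unname(tt$parameter)))
    },
    kruskal_wallis = {
      kt <- stats::kruskal.test(values, group)
      test_result("Kruskal-Wallis", unname(kt$statistic), kt$p.value,
                  as.integer(sizes),
                  sprintf("chi-square on %d df", unname(kt$parameter)))
    })
  out
}

test_result <- function(name, statistic, p, n, method, ...) {
  structure(list(test = name, statistic = statistic, p = p, n = n,
                 method = method, ...),
            class = "urostab_test")
}

#' @export
print.urostab_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$test, x$statistic, x$p, x$method, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Linear decay model of shared relative abundance
#'
#' Fits the study's temporal model: mean shared relative abundance (percent
#' scale) regressed on the collection interval in months, adjusted for age,
#' sex (F reference) and cancer status (optionally collection method).  With
#' one response row per subject a per-subject random intercept is confounded
#' with the residual, so the fixed effects are estimated by ordinary least
#' squares with Wald-t confidence intervals; an optional REML profile
#' (`method = "reml"`, via nlme) is available for replicated designs.
#'
#' @param summary an `overlap_summary` (or its `summary` data.frame).
#' @param terms predictors among `months`, `age`, `sex`, `cancer`, `method`
#'   (default the first four).  `months` maps to `interval_months`, `method`
#'   to the collection-method pair.
#' @param response response column (default `shared_abund_mean`); proportions
#'   are rescaled to percent.
#' @param method `"ols"` (default) or `"reml"`.
#' @return Object of class `decay_fit`: coefficient table with estimates,
#'   SEs, Wald-t 95% CIs, t statistics, df and p-values; marginal R^2
#'   (variance of fixed-effect predictions over variance of the response);
#'   standardized betas (continuous predictors z-scored, response untouched);
#'   `n`; and the underlying `lm`/`lme` fit.  Supports `coef()`, `confint()`,
#'   `predict()`, `residuals()`, `summary()` and `print()`.
#' @export
decay_model <- function(summary, terms = c("months", "age", "sex", "cancer"),
                        response = "shared_abund_mean",
                        method = c("ols", "reml")) {
  method <- match.arg(method)
  df <- if (inherits(summary, "overlap_summary")) summary$summary else summary
  allowed <- c("months", "age", "sex", "cancer", "method")
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0)
    ur_stop(paste0("unknown model terms: ", fmt_ids(bad)), "urostab_validation_error")
  dat <- data.frame(id = df$subject_id %||% seq_len(nrow(df)))
  dat$y <- df[[response]]
  if (max(dat$y, na.rm = TRUE) <= 1) dat$y <- 100 * dat$y  # percent scale
  if ("months" %in% terms) dat$months <- df$interval_months
  if ("age" %in% terms) dat$age <- df$age
  if ("sex" %in% terms) dat$sex <- factor(df$sex, levels = c("F", "M"))
  if ("cancer" %in% terms) dat$cancer <- as.numeric(df$cancer)
  if ("method" %in% terms)
    dat$method <- factor(df$method_pair, levels = c("MSU/MSU", "CATH/MSU"))
  if (anyNA(dat))
    ur_stop("missing covariate or response values", "urostab_validation_error")
  if (nrow(dat) <= length(terms) + 2)
    ur_stop("too few subjects for the requested model", "urostab_validation_error")

  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  if (method == "reml") {
    if (!requireNamespace("nlme", quietly = TRUE))
      ur_stop("the REML profile requires the nlme package", "urostab_validation_error")
    fit <- nlme::lme(fml, random = ~ 1 | id, data = dat, method = "REML")
    tt <- summary(fit)$tTable
    ct <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                     se = tt[, "Std.Error"], df = tt[, "DF"],
                     t = tt[, "t-value"], p = tt[, "p-value"],
                     stringsAsFactors = FALSE)
    fitted_fix <- stats::predict(fit, level = 0)
  } else {
    fit <- stats::lm(fml, data = dat)
    if (any(is.na(stats::coef(fit)))) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      ur_stop(paste0("rank-deficient design; aliased terms: ", fmt_ids(aliased)),
              "urostab_collinearity_error")
    }
    sm <- suppressWarnings(summary(fit))$coefficients
    ct <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     df = fit$df.residual, t = sm[, 3], p = sm[, 4],
                     stringsAsFactors = FALSE)
    fitted_fix <- stats::fitted(fit)
  }
  tcrit <- stats::qt(0.975, ct$df)
  ct$ci_lo <- ct$estimate - tcrit * ct$se
  ct$ci_hi <- ct$estimate + tcrit * ct$se
  rownames(ct) <- NULL
  marginal_r2 <- stats::var(fitted_fix) / stats::var(dat$y)

  # standardized betas: z-score continuous predictors only
  datz <- dat
  for (v in intersect(c("months", "age"), terms)) datz[[v]] <- as.numeric(scale(datz[[v]]))
  std <- if (method == "ols") stats::coef(stats::lm(fml, data = datz))
         else nlme::fixef(nlme::lme(fml, random = ~ 1 | id, data = datz, method = "REML"))
  std <- std[setdiff(names(std), "(Intercept)")]

  structure(list(coefficients = ct, marginal_r2 = unname(marginal_r2),
                 std_beta = std, n = nrow(dat), response = response,
                 response_scale = "percent", terms = terms, method = method,
                 fit = fit, data = dat),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Shared-abundance decay model (%s), n = %d subjects\n",
              toupper(x$method), x$n))
  cat(sprintf("response: %s (%% scale); marginal R2 = %.2f\n",
              x$response, x$marginal_r2))
  ct <- x$coefficients
  out <- data.frame(term = ct$term,
                    estimate = signif(ct$estimate, digits),
                    `95% CI` = sprintf("[%.*f, %.*f]", 2, ct$ci_lo, 2, ct$ci_hi),
                    t = signif(ct$t, digits), df = ct$df,
                    p = signif(ct$p, digits), check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat("standardized betas (predictors z-scored):\n")
  print(signif(object$std_beta, 3))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.decay_fit <- function(object, parm, level = 0.95, ...) {
  ct <- object$coefficients
  tcrit <- stats::qt(1 - (1 - level) / 2, ct$df)
  out <- cbind(ct$estimate - tcrit * ct$se, ct$estimate + tcrit * ct$se)
  dimnames(out) <- list(ct$term,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (object$method == "reml") stats::predict(object$fit, newdata, level = 0)
  else stats::predict(object$fit, newdata, ...)
}

#' @export
residuals.decay_fit <- function(object, ...) stats::residuals(object$fit)

#' Short- vs long-interval subgroup analysis
#'
#' Splits subjects at `split_months` (short group: interval <= split), reports
#' group means and SDs of the mean shared relative abundance (percent), and
#' fits the interval-only decay model within each group.
#'
#' @param summary an `overlap_summary` or its `summary` data.frame.
#' @param split_months split point in months (default 15).
#' @return List of class `interval_subgroups`: `groups` data.frame (`group`,
#'   `n`, `mean_pct`, `sd_pct`) and `fits`, a list of per-group
#'   interval-only [decay_model()] fits.
#' @export
interval_subgroup_analysis <- function(summary, split_months = 15) {
  df <- if (inherits(summary, "overlap_summary")) summary$summary else summary
  short <- df[df$interval_months <= split_months, , drop = FALSE]
  long <- df[df$interval_months > split_months, , drop = FALSE]
  if (nrow(short) == 0 || nrow(long) == 0)
    ur_stop(sprintf("split at %g months leaves an empty group", split_months),
            "urostab_validation_error")
  pct <- function(g) {
    v <- g$shared_abund_mean
    if (max(v, na.rm = TRUE) <= 1) v <- 100 * v
    v
  }
  groups <- data.frame(
    group = c(sprintf("<=%g months", split_months),
              sprintf(">%g months", split_months)),
    n = c(nrow(short), nrow(long)),
    mean_pct = c(mean(pct(short)), mean(pct(long))),
    sd_pct = c(stats::sd(pct(short)), stats::sd(pct(long))))
  try_fit <- function(g)  # a subgroup can be too small for its own slope fit
    tryCatch(decay_model(g, terms = "months"), urostab_error = function(e) NULL)
  fits <- list(short = try_fit(short), long = try_fit(long))
  structure(list(groups = groups, fits = fits, split_months = split_months),
            class = "interval_subgroups")
}

#' @export
print.interval_subgroups <- function(x, ...) {
  cat(sprintf("Shared abundance by collection-interval group (split %g months)\n",
              x$split_months))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s n = %2d  %.1f%% +/- %.1f%%\n",
                g$group[i], g$n[i], g$mean_pct[i], g$sd_pct[i]))
  for (nm in names(x$fits)) {
    if (is.null(x$fits[[nm]])) next
    ct <- x$fits[[nm]]$coefficients
    sl <- ct[ct$term == "months", ]
    cat(sprintf("  %s-interval slope: %.3f %%/month (p = %.3f)\n",
                nm, sl$estimate, sl$p))
  }
  invisible(x)
}
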
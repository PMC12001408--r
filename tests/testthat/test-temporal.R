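test_that("squared Pearson correlation and its t-test behave", {
  x <- 1:10
  perfect <- pearson_r2(x, 2 * x + 1)
  expect_equal(perfect$r_squared, 1)
  y <- c(1, -1, -1, 1)  # exactly orthogonal to a linear trend
  z <- 1:4
  expect_lt(pearson_r2(z, y)$r_squared, 1e-12)
  expect_error(pearson_r2(rep(1, 5), rnorm(5)), class = "urostab_degenerate_error")
  # p matches the t transform with n-2 df
  set.seed(70)
  a <- rnorm(20); b <- a + rnorm(20)
  res <- pearson_r2(a, b)
  tstat <- res$r * sqrt(18 / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
})

test_that("signed-rank test: hand cases and degenerate input", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p, 0.25)  # 2/8 patterns, doubled
  expect_equal(wilcoxon_signed_rank(c(1, -1) * 1.0,
                                    force = "approx")$p, 1, tolerance = 1e-9)
  expect_error(wilcoxon_signed_rank(c(0, 0)), class = "urostab_degenerate_error")
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3))$n, 3)
})

test_that("signed-rank exact p matches sign enumeration for n up to 20", {
  for (s in 1:60) {
    set.seed(s + 700)
    n <- sample(4:20, 1)
    d <- round(rnorm(n), 6)
    d <- d[!duplicated(abs(d)) & d != 0]
    if (length(d) < 3) next
    expect_equal(wilcoxon_signed_rank(d)$p, signrank_two_sided_p(d),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation is close to enumeration at the switch boundary", {
  set.seed(71)
  for (i in 1:10) {
    d <- rnorm(20)
    expect_lt(abs(wilcoxon_signed_rank(d, force = "approx")$p -
                    signrank_two_sided_p(d)), 0.01)
  }
})

test_that("rank-sum: identical groups, full separation, and exact enumeration", {
  expect_equal(group_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                          "wilcoxon_rank_sum")$p, 1)
  sep <- group_test(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
                    "wilcoxon_rank_sum")
  expect_equal(sep$p, 0.1)  # 2/C(6,3) two-sided
  # enumeration oracle over group assignments
  for (s in 1:30) {
    set.seed(s + 800)
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    v <- round(rnorm(nx + ny), 6)
    if (anyDuplicated(v)) next
    got <- group_test(v, rep(c("a", "b"), c(nx, ny)), "wilcoxon_rank_sum")$p
    r <- rank(v)
    w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ws <- apply(combn(nx + ny, nx), 2,
                function(i) sum(r[i]) - nx * (nx + 1) / 2)
    p_or <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
    expect_equal(got, p_or, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis on two groups maps to the squared rank-sum z", {
  set.seed(72)
  for (i in 1:10) {
    v <- rnorm(14)
    g <- rep(c("a", "b"), 7)
    kw <- group_test(v, g, "kruskal_wallis")
    r <- rank(v)
    nx <- 7; n <- 14
    z <- (sum(r[g == "a"]) - nx * (n + 1) / 2) /
      sqrt(nx * nx * (n + 1) / 12)
    expect_equal(unname(kw$statistic), z^2, tolerance = 1e-9)
    expect_equal(kw$p, pchisq(z^2, 1, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("t-test dispatch honours the Welch switch", {
  set.seed(73)
  v <- c(rnorm(8), rnorm(8, 1, 3))
  g <- rep(c("a", "b"), each = 8)
  welch <- group_test(v, g, "student_t", welch = TRUE)
  pooled <- group_test(v, g, "student_t", welch = FALSE)
  expect_false(isTRUE(all.equal(welch$p, pooled$p)))
  expect_error(group_test(c(1, 2), c("a", "b")), class = "urostab_validation_error")
})

make_overlap_df <- function(n = 30, seed = 1, slope = -0.66,
                            intercept = 99.78, noise = 0) {
  set.seed(seed)
  months <- runif(n, 3, 40)
  data.frame(
    subject_id = sprintf("p%02d", seq_len(n)),
    interval_months = months,
    age = runif(n, 30, 80),
    sex = sample(c("F", "M"), n, TRUE),
    cancer = sample(c(TRUE, FALSE), n, TRUE),
    method_pair = sample(c("MSU/MSU", "CATH/MSU"), n, TRUE),
    shared_abund_mean = pmin(pmax(
      (intercept + slope * months + rnorm(n, 0, noise)) / 100, 0), 1),
    n_shared = rpois(n, 40), stringsAsFactors = FALSE)
}

test_that("a noiseless linear response is interpolated exactly", {
  df <- make_overlap_df(n = 40)
  fit <- decay_model(df)
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), 99.78, tolerance = 1e-8)
  expect_equal(unname(cf["months"]), -0.66, tolerance = 1e-10)
  expect_equal(unname(cf["age"]), 0, tolerance = 1e-10)
  expect_equal(fit$marginal_r2, 1, tolerance = 1e-8)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= cf & cf <= ci[, 2]))
})

test_that("the months slope is invariant to centering the covariates", {
  df <- make_overlap_df(n = 50, noise = 8, seed = 2)
  f1 <- decay_model(df)
  df2 <- df
  df2$age <- df2$age - mean(df2$age)
  df2$interval_months <- df2$interval_months - mean(df2$interval_months)
  f2 <- decay_model(df2)
  expect_equal(coef(f1)[["months"]], coef(f2)[["months"]], tolerance = 1e-9)
})

test_that("standardized betas keep the raw sign and the method term is optional", {
  df <- make_overlap_df(n = 60, noise = 10, seed = 3)
  fit <- decay_model(df, terms = c("months", "age", "sex", "cancer", "method"))
  expect_true("methodCATH/MSU" %in% fit$coefficients$term)
  cf <- coef(fit)
  for (v in c("months", "age"))
    expect_equal(sign(fit$std_beta[[v]]), sign(cf[[v]]))
  # percent-scale responses are accepted as-is
  dfp <- df; dfp$shared_abund_mean <- 100 * dfp$shared_abund_mean
  expect_equal(coef(decay_model(dfp))[["months"]], coef(decay_model(df))[["months"]],
               tolerance = 1e-9)
})

test_that("rank-deficient designs raise a collinearity error naming the alias", {
  df <- make_overlap_df(n = 30, seed = 4)
  df$age <- df$interval_months  # age aliased with months
  expect_error(decay_model(df), "age", class = "urostab_collinearity_error")
  expect_error(decay_model(make_overlap_df(n = 5)),
               class = "urostab_validation_error")  # too few subjects
})

test_that("the REML profile reproduces OLS fixed effects on replicated data", {
  df <- make_overlap_df(n = 40, noise = 10, seed = 5)
  ols <- decay_model(df, terms = c("months", "age"))
  reml <- decay_model(df, terms = c("months", "age"), method = "reml")
  # one row per subject: the random intercept absorbs no information, point
  # estimates coincide with OLS
  expect_equal(coef(reml)[["months"]], coef(ols)[["months"]], tolerance = 1e-6)
})

test_that("interval subgroups report group means and per-group slopes", {
  df <- make_overlap_df(n = 60, noise = 5, seed = 6)
  sub <- interval_subgroup_analysis(df, split_months = 15)
  expect_equal(sum(sub$groups$n), 60)
  short <- df$interval_months <= 15
  expect_equal(sub$groups$mean_pct[1], mean(100 * df$shared_abund_mean[short]))
  expect_equal(sub$groups$sd_pct[2], sd(100 * df$shared_abund_mean[!short]))
  expect_named(sub$fits, c("short", "long"))
  # drift-free cohort: groups differ only by noise
  df0 <- make_overlap_df(n = 80, slope = 0, intercept = 70, noise = 10, seed = 7)
  s0 <- interval_subgroup_analysis(df0)
  pooled_se <- sqrt(sum(s0$groups$sd_pct^2 / s0$groups$n))
  expect_lt(abs(diff(s0$groups$mean_pct)), 3 * pooled_se)
  expect_error(interval_subgroup_analysis(df, split_months = 2),
               class = "urostab_validation_error")
})
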
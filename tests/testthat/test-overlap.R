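test_that("pair overlap matches hand computation", {
  t1 <- c(o1 = 0.5, o2 = 0.5, o3 = 0)
  t2 <- c(o1 = 0.3, o2 = 0, o3 = 0.7)
  row <- subject_overlap(t1, t2)
  expect_equal(row$n_shared, 1)
  expect_equal(row$shared_abund_t1, 0.5)
  expect_equal(row$shared_abund_t2, 0.3)
  expect_equal(row$shared_abund_mean, 0.4)
  expect_equal(row$frac_shared, 1 / 2)         # mean denominator: (2+2)/2
  expect_equal(subject_overlap(t1, t2, "union")$frac_shared, 1 / 3)
  expect_equal(subject_overlap(t1, t2, "min")$frac_shared, 1 / 2)
})

test_that("identical pairs give full overlap, disjoint pairs none", {
  x <- c(a = 0.2, b = 0.3, c = 0.5)
  ident <- subject_overlap(x, x)
  expect_equal(ident$frac_shared, 1)
  expect_equal(ident$shared_abund_mean, 1)
  d1 <- c(a = 1, b = 0); d2 <- c(a = 0, b = 1)
  dis <- subject_overlap(d1, d2)
  expect_equal(dis$n_shared, 0)
  expect_equal(dis$shared_abund_mean, 0)
  expect_error(subject_overlap(c(a = 1), c(b = 1)),
               class = "urostab_alignment_error")
})

test_that("shared abundance is symmetric and bounded, and full co-detection implies 1", {
  set.seed(41)
  for (i in 1:60) {
    k <- sample(3:12, 1)
    t1 <- rgamma(k, 0.5); t1 <- t1 / sum(t1)
    t2 <- rgamma(k, 0.5); t2 <- t2 / sum(t2)
    t1[runif(k) < 0.3] <- 0; t2[runif(k) < 0.3] <- 0
    if (sum(t1) == 0 || sum(t2) == 0) next
    t1 <- t1 / sum(t1); t2 <- t2 / sum(t2)
    names(t1) <- names(t2) <- paste0("o", seq_len(k))
    a <- subject_overlap(t1, t2); b <- subject_overlap(t2, t1)
    expect_equal(a$shared_abund_mean, b$shared_abund_mean)
    expect_lte(a$shared_abund_mean, 1 + 1e-12)
    expect_gte(a$shared_abund_mean, 0)
    expect_lte(a$n_shared, min(a$n_otus_t1, a$n_otus_t2))
    if (a$n_shared == a$n_otus_t1 && a$n_shared == a$n_otus_t2)
      expect_equal(a$shared_abund_mean, 1)
  }
})

test_that("adding a one-sample-only OTU never increases shared abundance", {
  set.seed(42)
  for (i in 1:40) {
    k <- sample(4:10, 1)
    t1 <- rgamma(k, 1); t1 <- t1 / sum(t1)
    t2 <- rgamma(k, 1); t2 <- t2 / sum(t2)
    names(t1) <- names(t2) <- paste0("o", seq_len(k))
    before <- subject_overlap(t1, t2)$shared_abund_mean
    eps <- runif(1, 0.01, 0.5)
    t1b <- c(t1, new = eps) / (1 + eps)
    t2b <- c(t2, new = 0)
    after <- subject_overlap(t1b, t2b)$shared_abund_mean
    expect_lte(after, before + 1e-12)
  }
})

test_that("cohort overlap reports per-subject rows and stratified aggregates", {
  # sub1: identical samples; sub2: half-overlapping
  m <- rbind(c(5, 5, 0, 0), c(5, 5, 0, 0),
             c(8, 2, 0, 0), c(8, 0, 2, 0))
  co <- tiny_cohort(m, n_subjects = 2, method1 = "CATHETER")
  ov <- cohort_overlap(co)
  expect_equal(nrow(ov$summary), 2)
  s1 <- ov$summary[ov$summary$subject_id == "sub1", ]
  expect_equal(s1$frac_shared, 1)
  expect_equal(s1$shared_abund_mean, 1)
  s2 <- ov$summary[ov$summary$subject_id == "sub2", ]
  expect_equal(s2$n_shared, 1)
  expect_equal(s2$shared_abund_mean, 0.8)
  expect_true(all(ov$summary$method_pair == "CATH/MSU"))
  agg <- ov$aggregates$overall
  expect_equal(agg[agg$statistic == "n_shared", "mean"], 1.5)
  expect_equal(agg[agg$statistic == "n_otus_per_sample", "mean"], 2)
  expect_true("sex=F" %in% names(ov$aggregates))
  expect_true("method_pair=CATH/MSU" %in% names(ov$aggregates))
})

test_that("a fully persistent drift-free synthetic cohort has near-total overlap", {
  cfg <- synthetic_config(n_subjects = 8, persistence_prob = 1,
                          shared_abund_slope_pct_per_month = 0,
                          shared_abund_noise_sd_pct = 0,
                          shared_abund_intercept_pct = 100,
                          subject_pool_mean = 30, subject_pool_sd = 5,
                          abundance_shape = 1,
                          depth_mean = 60000, depth_sd = 5000)
  g <- generate_cohort(cfg, seed = 3)
  ov <- cohort_overlap(qc_cohort(g$cohort)$cohort)
  expect_gt(min(ov$summary$frac_shared), 0.9)
  expect_gt(min(ov$summary$shared_abund_mean), 0.99)
})

test_that("prevalence requires detection in both samples and respects the cut", {
  # o1 persistent in everyone; o2 persistent only in sub1 (F); o3 never in both
  m <- rbind(c(5, 3, 1, 0), c(5, 2, 0, 1),
             c(5, 0, 2, 0), c(5, 0, 0, 2),
             c(5, 0, 1, 0), c(5, 0, 0, 1))
  tx <- c(o1 = "Staphylococcus", o2 = "Lactobacillus")
  co <- tiny_cohort(m, n_subjects = 3, taxonomy = tx)  # sexes F, M, F
  pt <- prevalence_table(co, min_prevalence = 0.5)
  expect_equal(pt$otu_id[1], "o1")
  expect_equal(pt[pt$otu_id == "o1", "pct_males"], 100)
  expect_equal(pt[pt$otu_id == "o1", "pct_females"], 100)
  expect_equal(pt[pt$otu_id == "o1", "label"], "Staphylococcus")
  expect_equal(pt[pt$otu_id == "o2", "n_present_females"], 1L)
  expect_false("o3" %in% pt$otu_id)                  # detected in both never
  expect_equal(nrow(prevalence_table(co, min_prevalence = 1.01)), 0)
  co_nosex <- co; co_nosex$subjects$sex <- NA_character_
  expect_error(prevalence_table(co_nosex), class = "urostab_validation_error")
})

test_that("dominant-discordant flags >threshold-in-one, absent-in-other OTUs", {
  t1 <- c(o1 = 0.8, o2 = 0.2); t2 <- c(o1 = 0, o2 = 1)
  expect_equal(dominant_discordant(t1, t2), "o1")
  expect_equal(dominant_discordant(t2, t1), "o1")           # direction-symmetric
  x <- c(o1 = 0.6, o2 = 0.4)
  expect_equal(dominant_discordant(x, x), character(0))
  b1 <- c(o1 = 0.5, o2 = 0.5); b2 <- c(o1 = 0, o2 = 1)
  expect_equal(dominant_discordant(b1, b2), character(0))   # 0.5 is not > 0.5
})
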
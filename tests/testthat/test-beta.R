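test_that("Bray-Curtis follows its definition on hand cases", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 0, 2)), 1)
  expect_equal(bray_curtis(c(2, 2, 0), c(0, 2, 2)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "urostab_undefined_distance_error")
  expect_error(bray_curtis(c(1, -1), c(1, 1)), class = "urostab_validation_error")
  expect_error(bray_curtis(c(1, 1), c(1, 1, 1)), class = "urostab_alignment_error")
})

test_that("the distance matrix equals elementwise pairwise calls and vegan", {
  m <- rbind(c(5, 5, 0), c(5, 5, 0), c(1, 2, 7))
  dimnames(m) <- list(paste0("s", 1:3), paste0("o", 1:3))
  rel <- to_relative_abundance(otu_counts(m))
  d <- as.matrix(distance_matrix(rel))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], bray_curtis(rel["s1", ], rel["s3", ]))
  for (s in 1:20) {
    set.seed(s + 500)
    tab <- otu_counts(random_counts(5, 25) + matrix(rbinom(125, 1, 0.2), 5))
    rel <- to_relative_abundance(tab)
    got <- as.matrix(distance_matrix(rel))
    want <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) if (i != j)
      want[i, j] <- sum(abs(rel[i, ] - rel[j, ])) / sum(rel[i, ] + rel[j, ])
    expect_equal(unname(got), want, tolerance = 1e-12)
    expect_equal(unname(got),
                 unname(as.matrix(vegan::vegdist(unclass(rel), "bray"))),
                 tolerance = 1e-12)
  }
})

test_that("PERMANOVA separates two clean groups with exact enumeration", {
  m <- rbind(matrix(rep(c(10, 0, 0, 5), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 10, 5, 0), 3), 3, byrow = TRUE))
  dimnames(m) <- list(paste0("s", 1:6), paste0("o", 1:4))
  d <- distance_matrix(to_relative_abundance(otu_counts(m)))
  des <- data.frame(sample_id = paste0("s", 1:6),
                    grp = rep(c("a", "b"), each = 3))
  res <- permanova(d, des, terms = "grp", permutations = "exact")
  expect_gt(res$R2[1], 0.999)
  # 72 of 720 label permutations preserve the partition (ties with F_obs)
  expect_equal(res$Pr_perm[1], 0.1)
  expect_equal(res$Pr_perm[1],
               permanova_oracle_exact_p(as.matrix(d), des$grp))
})

test_that("exact permutation p matches the independent enumeration oracle", {
  for (s in 1:10) {
    set.seed(s + 600)
    m <- random_counts(6, 15, lambda = 3, zero_frac = 0.4) + 1L
    d <- distance_matrix(to_relative_abundance(otu_counts(m)))
    grp <- rep(c("a", "b"), each = 3)
    res <- permanova(d, data.frame(sample_id = rownames(m), grp = grp),
                     terms = "grp", permutations = "exact")
    expect_equal(res$Pr_perm[1],
                 permanova_oracle_exact_p(as.matrix(d), grp),
                 tolerance = 1e-12)
    expect_equal(res$F[1], permanova_oracle_F(as.matrix(d), grp),
                 tolerance = 1e-10)
  }
})

test_that("the Gower identity holds: SS_total = sum(d^2)/n", {
  set.seed(55)
  m <- random_counts(8, 30) + 1L
  d <- distance_matrix(to_relative_abundance(otu_counts(m)))
  res <- permanova(d, data.frame(sample_id = rownames(m),
                                 grp = rep(c("a", "b"), 4)),
                   terms = "grp", permutations = 19)
  D <- as.matrix(d)
  expect_equal(res$SumOfSqs[res$term == "Total"],
               sum(D[lower.tri(D)]^2) / nrow(D), tolerance = 1e-9)
  expect_equal(sum(res$R2), 2, tolerance = 1e-9)  # terms+residual=1, total=1
})

test_that("PERMANOVA is invariant to simultaneous sample reordering", {
  set.seed(56)
  m <- random_counts(8, 20) + 1L
  des <- data.frame(sample_id = rownames(m), grp = rep(c("a", "b"), 4),
                    x = rnorm(8))
  d <- distance_matrix(to_relative_abundance(otu_counts(m)))
  res1 <- permanova(d, des, terms = c("grp", "x"), permutations = 99, seed = 4)
  p <- sample(8)
  m2 <- m[p, ]
  d2 <- distance_matrix(to_relative_abundance(otu_counts(m2)))
  res2 <- permanova(d2, des, terms = c("grp", "x"), permutations = 99, seed = 4)
  expect_equal(res1$SumOfSqs, res2$SumOfSqs, tolerance = 1e-9)
  expect_equal(res1$F, res2$F, tolerance = 1e-9)
})

test_that("for Euclidean distances the pseudo-F equals classical ANOVA F", {
  set.seed(57)
  y <- matrix(rnorm(12 * 2), 12, 2)
  grp <- rep(c("a", "b"), each = 6)
  d <- dist(y)
  attr(d, "Labels") <- sprintf("s%d", 1:12)
  res <- permanova(d, data.frame(sample_id = sprintf("s%d", 1:12), grp = grp),
                   terms = "grp", permutations = 19)
  # classical one-way MANOVA trace F on the coordinates
  fit <- lm(y ~ grp)
  ss_h <- sum((fitted(fit) - rep(colMeans(y), each = 12))^2)
  ss_e <- sum(residuals(fit)^2)
  expect_equal(res$F[1], (ss_h / 1) / (ss_e / 10), tolerance = 1e-9)
})

test_that("sequential results agree with vegan::adonis2 on random data", {
  set.seed(58)
  m <- random_counts(10, 40, lambda = 4, zero_frac = 0.3) + 1L
  rel <- to_relative_abundance(otu_counts(m))
  des <- data.frame(sample_id = rownames(m),
                    grp = rep(c("a", "b"), 5), x = rnorm(10))
  d <- distance_matrix(rel)
  mine <- permanova(d, des, terms = c("grp", "x"), permutations = 999, seed = 2)
  ref <- vegan::adonis2(unclass(rel) ~ grp + x, data = des, method = "bray",
                        permutations = 999, by = "terms")
  expect_equal(mine$SumOfSqs[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(mine$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(mine$Pr_perm[1:2], ref$`Pr(>F)`[1:2], tolerance = 0.08)
})

test_that("restricted permutations stay within strata", {
  set.seed(59)
  m <- random_counts(8, 20) + 1L
  des <- data.frame(sample_id = rownames(m), grp = rep(c("a", "b"), 4),
                    pair = rep(1:4, each = 2))
  d <- distance_matrix(to_relative_abundance(otu_counts(m)))
  res <- permanova(d, des, terms = "grp", permutations = "exact",
                   strata = "pair")
  # within-pair shuffles only: 2^4 = 16 admissible permutations... of 8! total
  expect_true(res$Pr_perm[1] >= 1 / 16 - 1e-12)
  expect_true(res$Pr_perm[1] <= 1)
})

test_that("degenerate designs are rejected", {
  set.seed(60)
  m <- random_counts(4, 10) + 1L
  d <- distance_matrix(to_relative_abundance(otu_counts(m)))
  des <- data.frame(sample_id = rownames(m), cst = "x",
                    grp = c("a", "a", "b", "b"),
                    grp2 = c("a", "a", "b", "b"),
                    uid = letters[1:4])
  expect_error(permanova(d, des, "cst", 9), class = "urostab_design_error")
  expect_error(permanova(d, des, c("grp", "grp2"), 9),
               class = "urostab_design_error")   # aliased
  expect_error(permanova(d, des, "uid", 9), class = "urostab_design_error")  # saturated
  expect_error(permanova(d, des, "nope", 9), class = "urostab_design_error")
})
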
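# independent oracles shared by the unit and acceptance suites; these never
# call the package's own implementations

# one-factor PERMANOVA pseudo-F from Anderson's direct within-group
# sums-of-squares identities on the raw distances (no Gower centering)
permanova_oracle_F <- function(D, grp) {
  n <- nrow(D)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  ss_within <- 0
  for (lev in unique(grp)) {
    i <- which(grp == lev)
    ss_within <- ss_within + sum(D[i, i][lower.tri(D[i, i])]^2) / length(i)
  }
  a <- length(unique(grp))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# exact permutation p by enumerating distinct group assignments
permanova_oracle_exact_p <- function(D, grp) {
  f_obs <- permanova_oracle_F(D, grp)
  perms <- combn(length(grp), sum(grp == grp[1]))
  fs <- apply(perms, 2, function(i) {
    g <- rep("b", length(grp)); g[i] <- "a"
    permanova_oracle_F(D, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# exact signed-rank null from the generating polynomial prod_r (1 + x^r):
# counts of sign patterns by the positive-rank sum V
signrank_counts <- function(n) {
  counts <- 1
  for (r in seq_len(n)) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
  counts  # index v+1 holds #patterns with V = v
}

signrank_two_sided_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  v <- sum(rank(abs(d))[d > 0])
  cnt <- signrank_counts(n)
  lo <- sum(cnt[seq_len(v + 1)]) / 2^n          # P(V <= v)
  hi <- sum(cnt[seq(v + 1, length(cnt))]) / 2^n # P(V >= v)
  min(1, 2 * min(lo, hi))
}

# exact rank-sum two-sided p by enumerating C(n, nx) group assignments
ranksum_two_sided_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  perms <- combn(n, nx)
  ws <- colSums(matrix(r[perms], nrow = nx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
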
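#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`; 0 for identical composition, 1 for
#' disjoint supports.
#'
#' @param x,y non-negative abundance vectors over the same OTU index.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(2, 2, 0), c(0, 2, 2))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    ur_stop("vectors must share one OTU index", "urostab_alignment_error")
  if (any(x < 0) || any(y < 0))
    ur_stop("abundances must be non-negative", "urostab_validation_error")
  denom <- sum(x) + sum(y)
  if (denom == 0)
    ur_stop("Bray-Curtis is undefined when both samples are all-zero",
            "urostab_undefined_distance_error")
  sum(abs(x - y)) / denom
}

#' All-pairs Bray-Curtis distance matrix
#'
#' @param table a `rel_abundance` matrix (or `otu_counts`, normalized first).
#' @return A [stats::dist] object labelled with sample ids, with attribute
#'   `metric = "bray_curtis"`.
#' @export
distance_matrix <- function(table) {
  if (inherits(table, "otu_counts")) table <- to_relative_abundance(table)
  m <- unclass(table)
  if (nrow(m) < 2)
    ur_stop("need at least two samples", "urostab_validation_error")
  if (any(rowSums(m) == 0))
    ur_stop(paste0("all-zero sample(s): ", fmt_ids(rownames(m)[rowSums(m) == 0])),
            "urostab_undefined_distance_error")
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rowSums(m), rowSums(m), "+")
  d <- stats::as.dist(num / den)
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a dissimilarity matrix among design
#' terms (McArdle-Anderson): the squared distances are Gower-centered into an
#' inner-product matrix `G`, each term's sequential (Type-I) sum of squares is
#' the trace of `G` projected onto the term's design columns, and
#' `pseudo-F = (SS_term/df_term) / (SS_res/df_res)`.  Significance is assessed
#' by permuting sample labels, optionally within `strata`; the p-value uses
#' the add-one estimator `(1 + #{F* >= F}) / (1 + n_permutations)` so it is
#' never exactly zero.  With `permutations = "exact"` all `n!` label
#' permutations are enumerated and the p-value is the exact proportion
#' `#{F* >= F} / n!` (the identity counts itself).
#'
#' @param d a `dist` object (e.g. from [distance_matrix()]).
#' @param design data.frame of factors/covariates; if it has a `sample_id`
#'   column or rownames they are matched against the labels of `d`, otherwise
#'   rows must already be in `d`'s order.
#' @param terms character vector of design columns, fitted sequentially.
#' @param permutations integer count (default 999) or `"exact"`.
#' @param seed integer seed for the permutation stream.
#' @param strata optional design column name: permutations are restricted to
#'   shuffles within each stratum.
#' @return Object of class `permanova_table`: data.frame with one row per
#'   term plus `Residual` and `Total` (`Df`, `SumOfSqs`, `R2`, `F`,
#'   `Pr_perm`), and attributes `n_permutations`, `seed`, `exact`.
#' @export
permanova <- function(d, design, terms, permutations = 999, seed = 1,
                      strata = NULL) {
  stopifnot(inherits(d, "dist"))
  D <- as.matrix(d)
  n <- nrow(D)
  lbl <- labels(d) %||% rownames(D)
  if (!is.null(lbl) && !is.null(design$sample_id)) {
    if (!setequal(lbl, design$sample_id))
      ur_stop("design sample_id set differs from distance labels",
              "urostab_alignment_error")
    design <- design[match(lbl, design$sample_id), , drop = FALSE]
  } else if (!is.null(lbl) && !is.null(rownames(design)) &&
             setequal(rownames(design), lbl)) {
    design <- design[lbl, , drop = FALSE]
  } else if (nrow(design) != n) {
    ur_stop("design rows do not align with the distance matrix",
            "urostab_alignment_error")
  }
  missing_terms <- setdiff(c(terms, strata), colnames(design))
  if (length(missing_terms) > 0)
    ur_stop(paste0("terms not in design: ", fmt_ids(missing_terms)),
            "urostab_design_error")

  # Gower-centered inner-product matrix
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ss_total <- sum(diag(G))

  # sequential hat matrices for [1 | X_1 | ... | X_k]
  X <- matrix(1, n, 1)
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  rank_prev <- 1L
  for (k in seq_along(terms)) {
    v <- design[[terms[k]]]
    if (length(unique(v)) < 2)
      ur_stop(paste0("term '", terms[k], "' is constant"), "urostab_design_error")
    mm <- if (is.numeric(v)) matrix(as.numeric(v), n, 1)
          else stats::model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    X <- cbind(X, mm)
    qx <- qr(X)
    dfs[k] <- qx$rank - rank_prev
    if (dfs[k] == 0)
      ur_stop(paste0("term '", terms[k], "' is aliased with earlier terms"),
              "urostab_design_error")
    rank_prev <- qx$rank
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
  }
  df_res <- n - rank_prev
  if (df_res <= 0)
    ur_stop("model is saturated: zero residual degrees of freedom",
            "urostab_design_error")

  stat_fun <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- max(ss_total - tr[length(tr)], 0)  # roundoff floor
    (ss / dfs) / (ss_res / df_res)
  }
  F_obs <- stat_fun(G)
  tr_obs <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss_obs <- diff(c(0, tr_obs))
  ss_res <- max(ss_total - tr_obs[length(tr_obs)], 0)

  strata_f <- if (!is.null(strata)) factor(design[[strata]]) else NULL
  exact <- identical(permutations, "exact")
  if (exact) {
    if (n > 8)
      ur_stop("exact enumeration supported up to n = 8 samples",
              "urostab_design_error")
    perms <- all_permutations(n)
    if (!is.null(strata_f))
      perms <- perms[apply(perms, 1, function(p) all(strata_f[p] == strata_f)), ,
                     drop = FALSE]
    Fs <- apply(perms, 1, function(p) stat_fun(G[p, p]))
    Fs <- matrix(Fs, nrow = length(terms))
    pvals <- rowMeans(Fs >= f_floor(F_obs))     # includes identity
    n_perm_used <- ncol(Fs)
  } else {
    n_perm_used <- as.integer(permutations)
    old <- get0(".Random.seed", globalenv())
    set.seed(seed)
    exceed <- numeric(length(terms))
    for (b in seq_len(n_perm_used)) {
      p <- permute_indices(n, strata_f)
      exceed <- exceed + (stat_fun(G[p, p]) >= f_floor(F_obs))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pvals <- (1 + exceed) / (1 + n_perm_used)
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(dfs, df_res, n - 1L),
    SumOfSqs = c(ss_obs, ss_res, ss_total),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    F = c(F_obs, NA, NA),
    Pr_perm = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, n_permutations = n_perm_used, seed = seed, exact = exact,
            class = c("permanova_table", "data.frame"))
}

#' @export
print.permanova_table <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (%s permutations%s)\n",
              format(attr(x, "n_permutations")),
              if (isTRUE(attr(x, "exact"))) ", exact enumeration" else ""))
  df <- as.data.frame(x)
  df$SumOfSqs <- signif(df$SumOfSqs, digits)
  df$R2 <- signif(df$R2, digits)
  df$F <- signif(df$F, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# tie floor: a permuted statistic within float jitter of the observed one
# counts as >= (same guard vegan applies), so genuine ties are never missed
f_floor <- function(f)
  ifelse(is.finite(f), f - pmax(sqrt(.Machine$double.eps), 1e-10 * abs(f)), f)

# random permutation, free or within strata
permute_indices <- function(n, strata_f = NULL) {
  if (is.null(strata_f)) return(sample.int(n))
  p <- seq_len(n)
  for (lev in levels(strata_f)) {
    i <- which(strata_f == lev)
    p[i] <- i[sample.int(length(i))]
  }
  p
}

# all n! permutations as a matrix (rows)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}
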
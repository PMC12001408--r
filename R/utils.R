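# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers/tests can distinguish failure modes
ur_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "urostab_error")))
}

ur_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "urostab_warning")))
}

# locale-independent lexicographic order (radix = C collation) so canonical
# id ordering is identical on every machine
id_order <- function(x) {
  if (is.null(x) || length(x) == 0) return(integer(0))
  order(x, method = "radix")
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# deterministic per-sample RNG stream: hash (seed, sample_id) into a 31-bit
# seed so rarefaction results do not depend on cohort ordering
stream_seed <- function(seed, sample_id) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(sample_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# format a few ids for an error message
fmt_ids <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
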
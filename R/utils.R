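# Internal numeric helpers shared across modules.

# Population (divide-by-n) standard deviation of a vector.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# Column-wise population SD of a matrix.
col_sd_pop <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu)^2) / n)
}

# Z-score columns with the population convention. Columns whose SD falls
# below `tol` are left centered (not divided) and reported via attribute
# "degenerate" so callers can drop or flag them.
zscore_pop <- function(m, tol = 1e-12) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- col_sd_pop(m)
  degenerate <- s < tol
  s_safe <- ifelse(degenerate, 1, s)
  out <- sweep(sweep(m, 2L, mu), 2L, s_safe, "/")
  attr(out, "degenerate") <- degenerate
  out
}

# Cosine similarity between two vectors.
cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
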
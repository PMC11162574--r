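# Brute-force definitional oracles, kept deliberately naive and independent
# of the implementation paths they check.

oracle_euclidean <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - q[i])^2
  sqrt(s)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

oracle_student_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Benjamini-Hochberg step-up from its definition:
# q_(i) = min(1, min_{k >= i} p_(k) * m / k) on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in m:1) {
    cand <- ps[i] * m / i
    q[i] <- if (i == m) min(1, cand) else min(q[i + 1], cand, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_tau <- function(x) {
  m <- max(x)
  s <- 0
  for (i in seq_along(x)) s <- s + (1 - x[i] / m)
  s / (length(x) - 1)
}
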
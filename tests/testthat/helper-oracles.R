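# Independent brute-force oracles (textbook formulas), kept free of any
# package code path they are used to check.

oracle_welch <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

oracle_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
}

# hand step-up: q_(i) = min(1, min_{j >= i} p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[i] <- min(1, min(ps[j] * m / j))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
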
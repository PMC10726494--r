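# Independent brute-force oracles. These deliberately use plain loops and
# textbook formulas, never the package's own vectorized code paths.

oracle_prop <- function(a, b) {
  n <- length(a)
  pp <- 0; qq <- 0; p1 <- 0; p2 <- 0
  for (i in seq_len(n)) {
    if (a[i] == 1 && b[i] == 1) pp <- pp + 1
    if (a[i] == 0 && b[i] == 0) qq <- qq + 1
    if (a[i] == 1) p1 <- p1 + 1
    if (b[i] == 1) p2 <- p2 + 1
  }
  c(prop_p_1 = p1 / n, prop_p_2 = p2 / n, prop_q_1 = 1 - p1 / n,
    prop_q_2 = 1 - p2 / n, prop_pp = pp / n, prop_qq = qq / n,
    same_state = (pp + qq) / n)
}

oracle_ratio <- function(n1, n2) {
  if (n1 == 0 && n2 == 0) return(NA_real_)
  if (n1 <= n2) n1 / n2 else n2 / n1
}

# Welch statistic straight from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
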
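# Independent oracles, deliberately implemented without the code paths
# they check.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins. Probabilities computed from
# binomial coefficients directly.
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0L, c1 - r2):min(r1, c1)
  prob <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Welch t from closed form, with the two-sided p computed through the
# regularized incomplete beta function instead of pt().
welch_closed_form <- function(x, y, conf_level = 0.95) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- stats::pbeta(df / (df + t^2), df / 2, 0.5)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(
    t = t, df = df, p = p,
    ci = mean(x) - mean(y) + c(-1, 1) * tcrit * sqrt(se2)
  )
}

# Step-up BH computed literally from the sorted definition.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
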
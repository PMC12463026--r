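# Shared fixtures, built in code.

# Small fixed study table with distinct standard errors.
toy_studies <- function() {
  tibble::tibble(
    study_id = 1:5,
    effect = c(0.5, 0.3, 1.2, -0.2, 0.8),
    se = c(1.1, 1.9, 3.3, 2.4, 2.8)
  )
}

# One simulated meta-analysis from a given cell.
make_dataset <- function(n = 15, severity = 1 / 3, tau2 = 0,
                         selection = "p_value", seed = 42, replicate = 1,
                         favor = "positive") {
  cfg <- scenario_config(n, severity = severity, tau2 = tau2,
                         selection = selection, seed = seed, favor = favor)
  generate_dataset(cfg, replicate_id = replicate)
}

# Independent OLS oracle via explicit normal equations: intercept estimate,
# its standard error, t statistic and two-sided p on n - 2 df.
ols_intercept_oracle <- function(xv, yv) {
  n <- length(xv)
  X <- cbind(1, xv)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% yv
  resid <- yv - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se_b0 <- sqrt(s2 * xtx_inv[1, 1])
  t0 <- beta[1] / se_b0
  list(intercept = beta[1], t = t0, p = 2 * pt(-abs(t0), n - 2))
}

# Brute-force Kendall concordance counts between Begg's standardised
# deviates and the variances, enumerating every pair with a double loop.
begg_pairs_oracle <- function(effect, se) {
  v <- se^2
  w <- 1 / v
  mu <- sum(w * effect) / sum(w)
  t_i <- (effect - mu) / sqrt(v - 1 / sum(w))
  P <- 0L
  Q <- 0L
  n <- length(effect)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(t_i[j] - t_i[i]) * sign(v[j] - v[i])
      if (s > 0) P <- P + 1L
      if (s < 0) Q <- Q + 1L
    }
  }
  list(P = P, Q = Q)
}

# One trim-and-fill L0 step executed "on paper": centre at the fixed-effect
# mean, rank absolute deviations, rank-sum of the dominant side, L0, k0.
trimfill_one_step_oracle <- function(effect, se) {
  w <- 1 / se^2
  mu <- sum(w * effect) / sum(w)
  d <- effect - mu
  r <- rank(abs(d))
  t_n <- max(sum(r[d > 0]), sum(r[d < 0]))
  n <- length(effect)
  l0 <- (4 * t_n - n * (n + 1)) / (2 * n - 1)
  max(0, floor(l0 + 0.5))
}
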
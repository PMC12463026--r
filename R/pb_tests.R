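#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardised effects \eqn{z_i = y_i/s_i} on
#' the precisions \eqn{x_i = 1/s_i}; the test statistic is the t statistic
#' of the intercept on \eqn{n - 2} degrees of freedom (two-sided). A
#' non-zero intercept indicates small-study asymmetry: imprecise studies
#' reporting systematically larger standardised effects than precise ones.
#'
#' @param data Data frame with columns `effect` and `se`; at least 3 studies
#'   with at least two distinct standard errors.
#' @param alpha Two-sided significance level for the binary flag.
#' @return An object of class `pb_test` with fields `method`, `statistic`
#'   (intercept t), `p_value`, `df`, `intercept`, `slope`, `flagged`,
#'   `alpha`, `k`.
#' @export
#' @examples
#' studies <- withr::with_seed(1, simulate_study_pool(20))
#' egger_test(studies)
egger_test <- function(data, alpha = 0.05) {
  tbl <- as_study_tbl(data, min_n = 3L)
  if (length(unique(tbl$se)) < 2) {
    rlang::abort("Egger's regression is degenerate: all standard errors are identical.")
  }
  z <- tbl$effect / tbl$se
  x <- 1 / tbl$se
  fit <- stats::lm(z ~ x)
  sm <- summary(fit)$coefficients
  t_stat <- sm["(Intercept)", "t value"]
  df <- length(z) - 2L
  p <- 2 * stats::pt(-abs(t_stat), df)
  new_pb_test(
    method = "egger",
    statistic = t_stat,
    p_value = p,
    flagged = p < alpha,
    alpha = alpha,
    k = nrow(tbl),
    extra = list(df = df,
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope = unname(sm["x", "Estimate"]))
  )
}

#' Begg and Mazumdar's rank correlation test
#'
#' Tests for association between standardised deviates and study variances.
#' The effects are centred at the fixed-effect pooled mean
#' \eqn{\hat\mu_{FE}} (weights \eqn{1/s_i^2}) and standardised by
#' \eqn{\sqrt{s_i^2 - (\sum_j 1/s_j^2)^{-1}}}, the variance of
#' \eqn{y_i - \hat\mu_{FE}}. Kendall concordance between the deviates and
#' the variances is counted over all pairs, and the statistic is the normal
#' approximation \eqn{z = (P - Q \mp c)/\sqrt{n(n-1)(2n+5)/18}} with an
#' optional continuity correction \eqn{c = 1} applied towards zero.
#'
#' @param data Data frame with columns `effect` and `se`; at least 3 studies.
#' @param alpha Two-sided significance level for the binary flag.
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return A `pb_test` with fields `statistic` (z), `p_value`, `P`, `Q`,
#'   `flagged`.
#' @export
#' @examples
#' studies <- withr::with_seed(1, simulate_study_pool(20))
#' begg_test(studies)
begg_test <- function(data, alpha = 0.05, continuity = TRUE) {
  tbl <- as_study_tbl(data, min_n = 3L)
  y <- tbl$effect
  v <- tbl$se^2
  n <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  v_star <- v - 1 / sum(w)
  if (any(v_star <= 0)) {
    rlang::abort("Degenerate variance: some s_i^2 do not exceed the pooled-mean variance.")
  }
  t_i <- (y - mu_fe) / sqrt(v_star)
  # Kendall concordance over all pairs between deviates and variances
  st <- sign(outer(t_i, t_i, "-"))
  sv <- sign(outer(v, v, "-"))
  prod_upper <- (st * sv)[upper.tri(st)]
  p_conc <- sum(prod_upper > 0)
  q_disc <- sum(prod_upper < 0)
  d <- p_conc - q_disc
  cc <- if (continuity && abs(d) >= 1) 1 else 0
  z <- (abs(d) - cc) / sqrt(n * (n - 1) * (2 * n + 5) / 18) * sign(d)
  if (d == 0) z <- 0
  p <- 2 * stats::pnorm(-abs(z))
  new_pb_test(
    method = "begg",
    statistic = z,
    p_value = p,
    flagged = p < alpha,
    alpha = alpha,
    k = n,
    extra = list(P = p_conc, Q = q_disc, continuity = continuity)
  )
}

#' Trim-and-fill estimate of suppressed studies
#'
#' Duval and Tweedie's nonparametric funnel-symmetry method with
#' fixed-effect centring. Iteratively: centre the effects at the current
#' fixed-effect estimate of the trimmed data, rank the absolute deviations
#' of all studies, take the side with the larger rank sum as dominant,
#' compute the missing-study estimator on that side — the default rank-sum
#' estimator is \eqn{L_0 = (4 T_n - n(n+1))/(2n-1)} with \eqn{T_n} the rank
#' sum of the dominant side; \eqn{R_0} is the rightmost-run alternative —
#' trim `k0 = max(0, round(estimator))` extreme studies from that side and
#' re-estimate, until `k0` stabilises. There is no p-value; the binary flag
#' is `k0 > 0`, the only parameter-free decision rule the method admits.
#' Note this makes the flag very liberal: symmetric sampling noise alone
#' produces `k0 > 0` in a large fraction of unbiased meta-analyses.
#'
#' @param data Data frame with columns `effect` and `se`; at least 3 studies.
#' @param estimator `"L0"` (rank-sum, default) or `"R0"` (rightmost run).
#' @param max_iter Iteration cap; on an oscillation the last `k0` is
#'   returned with `converged = FALSE`.
#' @param alpha Carried along for interface symmetry; unused by the flag.
#' @return A `pb_test` with fields `k0`, `side` (+1 when the right/positive
#'   side dominates), `converged`, `mu_trimmed` (fixed-effect estimate of
#'   the trimmed data) and `flagged = k0 > 0`; `statistic` is `k0` and
#'   `p_value` is `NA`.
#' @export
#' @examples
#' studies <- withr::with_seed(1, simulate_study_pool(20))
#' trim_and_fill(studies)
trim_and_fill <- function(data, estimator = c("L0", "R0"), max_iter = 50L,
                          alpha = 0.05) {
  estimator <- rlang::arg_match(estimator)
  tbl <- as_study_tbl(data, min_n = 3L)
  y <- tbl$effect
  s <- tbl$se
  n <- length(y)
  fe <- function(idx) {
    w <- 1 / s[idx]^2
    sum(w * y[idx]) / sum(w)
  }

  k0 <- 0L
  mu <- fe(seq_len(n))
  side <- 1
  converged <- FALSE
  seen <- integer(0)
  for (it in seq_len(max_iter)) {
    d <- y - mu
    r <- rank(abs(d))
    t_pos <- sum(r[d > 0])
    t_neg <- sum(r[d < 0])
    side <- if (t_pos >= t_neg) 1 else -1
    t_n <- max(t_pos, t_neg)
    est <- switch(estimator,
      L0 = (4 * t_n - n * (n + 1)) / (2 * n - 1),
      R0 = rightmost_run(d * side, r) - 1
    )
    k0_new <- max(0L, as.integer(round_half_up(max(est, 0))))
    k0_new <- min(k0_new, n - 1L)
    if (it > 1 && k0_new == k0) {
      converged <- TRUE
      break
    }
    if (k0_new %in% seen) {
      # oscillation: keep the last value, flag non-convergence
      k0 <- k0_new
      break
    }
    seen <- c(seen, k0)
    k0 <- k0_new
    keep <- seq_len(n)
    if (k0 > 0) {
      trim_order <- order(side * (y - mu), decreasing = TRUE)
      keep <- setdiff(keep, trim_order[seq_len(k0)])
    }
    mu <- fe(keep)
  }
  new_pb_test(
    method = "trim_fill",
    statistic = as.numeric(k0),
    p_value = NA_real_,
    flagged = k0 > 0,
    alpha = alpha,
    k = n,
    extra = list(k0 = k0, side = side, converged = converged,
                 estimator = estimator, mu_trimmed = mu)
  )
}

# Length of the run of largest |deviation| ranks all lying on the dominant
# side: count down from the top rank while deviations stay positive (the
# input is pre-multiplied by the dominant side's sign).
rightmost_run <- function(d_signed, r) {
  ord <- order(r, decreasing = TRUE)
  run <- 0L
  for (i in ord) {
    if (d_signed[i] > 0) run <- run + 1L else break
  }
  run
}

new_pb_test <- function(method, statistic, p_value, flagged, alpha, k, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value,
           flagged = flagged, alpha = alpha, k = k), extra),
    class = "pb_test"
  )
}

#' @export
print.pb_test <- function(x, ...) {
  label <- c(egger = "Egger's regression test",
             begg = "Begg's rank correlation test",
             trim_fill = "Trim-and-fill")[x$method]
  cat("<pb_test>", label, "\n")
  if (x$method == "trim_fill") {
    cat(sprintf("  k0 = %d imputed studies on the %s side (%s)\n",
                x$k0, if (x$side > 0) "left" else "right",
                if (x$converged) "converged" else "not converged"))
  } else {
    cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  }
  cat(sprintf("  publication bias flagged: %s (k = %d studies)\n",
              if (x$flagged) "YES" else "no", x$k))
  invisible(x)
}

#' Tidy a publication-bias test
#'
#' @param x A `pb_test`.
#' @param ... Unused.
#' @return A one-row tibble with columns `method`, `statistic`, `p_value`,
#'   `k0`, `flagged`.
#' @method tidy pb_test
#' @export
tidy.pb_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    k0 = if (x$method == "trim_fill") as.integer(x$k0) else NA_integer_,
    flagged = x$flagged
  )
}

#' Run all three traditional publication-bias tests
#'
#' Convenience wrapper applying [egger_test()], [begg_test()] and
#' [trim_and_fill()] to the same study table.
#'
#' @param data Data frame with columns `effect` and `se`.
#' @param alpha Two-sided significance level.
#' @param continuity Continuity correction for Begg's test.
#' @return A tibble with one row per method (columns as in [tidy.pb_test()]).
#' @export
#' @examples
#' studies <- withr::with_seed(1, simulate_study_pool(20))
#' pb_test_all(studies)
pb_test_all <- function(data, alpha = 0.05, continuity = TRUE) {
  dplyr::bind_rows(
    tidy(egger_test(data, alpha = alpha)),
    tidy(begg_test(data, alpha = alpha, continuity = continuity)),
    tidy(trim_and_fill(data, alpha = alpha))
  )
}
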
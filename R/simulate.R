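#' Simulate a pool of study-level results
#'
#' Draws independent studies from the hierarchical normal-normal model used
#' throughout the package: within-study standard errors
#' \eqn{s_i \sim \mathrm{Uniform}(1, 4)}, study-specific true effects
#' \eqn{\mu_i \sim N(\mu, \tau^2)}, and observed effects
#' \eqn{y_i \sim N(\mu_i, s_i^2)}. A two-sided p-value against
#' \eqn{H_0\colon y_i = 0} is attached to each study
#' (\eqn{p = 2\{1 - \Phi(|y_i/s_i|)\}}).
#'
#' Draws consume the current R random-number stream; wrap in
#' [withr::with_seed()] or call [set.seed()] for reproducibility.
#'
#' @param total Number of studies to draw (at least 2).
#' @param mu True overall effect \eqn{\mu}; the benchmark design uses 0.
#' @param tau2 Between-study variance \eqn{\tau^2 \ge 0}; the benchmark grid
#'   uses 0 (homogeneous) and 1 (heterogeneous).
#' @param se_range Support of the uniform distribution of the within-study
#'   standard errors; `c(1, 4)` mirrors the mix of small and large studies
#'   seen in practice.
#' @return A tibble with columns `study_id`, `effect`, `se`, `p_two_sided`.
#' @export
#' @examples
#' withr::with_seed(1, simulate_study_pool(5))
simulate_study_pool <- function(total, mu = 0, tau2 = 0, se_range = c(1, 4)) {
  if (!is.numeric(total) || length(total) != 1 || total < 2) {
    rlang::abort("`total` must be a single integer >= 2.")
  }
  if (tau2 < 0) {
    rlang::abort("`tau2` must be non-negative.")
  }
  total <- as.integer(total)
  se <- stats::runif(total, se_range[1], se_range[2])
  mu_i <- stats::rnorm(total, mu, sqrt(tau2))
  effect <- stats::rnorm(total, mu_i, se)
  tibble::tibble(
    study_id = seq_len(total),
    effect = effect,
    se = se,
    p_two_sided = 2 * stats::pnorm(-abs(effect / se))
  )
}

#' Describe one simulation cell
#'
#' A scenario configuration fixes everything that defines a cell of the
#' simulation grid: the number of published studies `n_published`, the
#' suppression severity (the ratio m/n of unpublished to published studies),
#' the between-study variance, the selection mechanism and its direction,
#' and the significance level.
#'
#' The number of suppressed studies is `round_half_up(severity * n_published)`
#' by default (so severity 1/10 at n = 15 suppresses 2 studies); set
#' `rounding = "floor"` for the truncating variant.
#'
#' @param n_published Number of published studies n (the funnel-plot studies).
#' @param severity Ratio m/n of suppressed to published studies; the
#'   benchmark grid uses 0 (no bias), 1/10 (mild), 1/5 (moderate) and
#'   1/3 (severe). Must be 0 exactly when `selection = "none"`.
#' @param tau2 Between-study variance.
#' @param selection Suppression mechanism: `"none"`, `"p_value"` (the least
#'   significant results go unpublished) or `"effect_size"` (the smallest
#'   effects go unpublished).
#' @param mu True overall effect.
#' @param alpha Two-sided significance level used by the p-value ranking and
#'   inherited by detectors (0.05).
#' @param seed Optional integer seed; when set, [generate_dataset()] derives
#'   a per-replicate stream from it, otherwise the ambient RNG is used.
#' @param favor Direction of suppression. `"positive"` (default) suppresses
#'   the least favourable results — the most negative / least significant in
#'   the positive direction — which is what creates funnel asymmetry when the
#'   true effect is 0. `"none"` is the symmetric variant that ranks by
#'   two-sided p-value or absolute effect size; it hollows out the funnel
#'   without tilting it, so asymmetry tests retain only their type-I rate
#'   against it (see the methods vignette).
#' @param rounding How `severity * n_published` is turned into an integer
#'   count of suppressed studies.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config(15, severity = 1/3, tau2 = 0, selection = "p_value")
scenario_config <- function(n_published,
                            severity = 0,
                            tau2 = 0,
                            selection = c("none", "p_value", "effect_size"),
                            mu = 0,
                            alpha = 0.05,
                            seed = NULL,
                            favor = c("positive", "none"),
                            rounding = c("half_up", "floor")) {
  selection <- rlang::arg_match(selection)
  favor <- rlang::arg_match(favor)
  rounding <- rlang::arg_match(rounding)
  if (!is.numeric(n_published) || length(n_published) != 1 || n_published < 2) {
    rlang::abort("`n_published` must be a single integer >= 2.")
  }
  if (severity < 0 || severity >= 1) {
    rlang::abort("`severity` must lie in [0, 1).")
  }
  if ((severity == 0) != (selection == "none")) {
    rlang::abort("`severity` must be 0 if and only if `selection` is \"none\".")
  }
  if (tau2 < 0) rlang::abort("`tau2` must be non-negative.")
  m_removed <- switch(rounding,
    half_up = round_half_up(severity * n_published),
    floor = as.integer(floor(severity * n_published))
  )
  if (severity > 0 && m_removed < 1) {
    rlang::abort("`severity` > 0 must suppress at least one study; increase `n_published`.")
  }
  structure(
    list(
      n_published = as.integer(n_published),
      severity = severity,
      tau2 = tau2,
      selection = selection,
      mu = mu,
      alpha = alpha,
      seed = if (!is.null(seed)) as.integer(seed),
      favor = favor,
      rounding = rounding,
      m_removed = m_removed
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n published: %d, suppressed: %d (severity %.3g)\n",
              x$n_published, x$m_removed, x$severity))
  cat(sprintf("  tau2: %.3g, mu: %.3g, alpha: %.3g\n", x$tau2, x$mu, x$alpha))
  cat(sprintf("  selection: %s (favor = %s)\n", x$selection, x$favor))
  invisible(x)
}

# Ranking key for suppression: studies with the LARGEST key are suppressed.
selection_key <- function(pool, selection, favor) {
  z <- pool$effect / pool$se
  switch(selection,
    p_value = if (favor == "positive") 1 - stats::pnorm(z) else pool$p_two_sided,
    effect_size = if (favor == "positive") -pool$effect else -abs(pool$effect)
  )
}

#' Split a study pool into published and unpublished studies
#'
#' Deterministically suppresses the `m_removed` studies with the least
#' favourable results. Under `selection = "p_value"` favourability is
#' significance (one-sided towards positive effects by default); under
#' `selection = "effect_size"` it is the size of the effect (signed by
#' default). Ties are broken by absolute effect size (ascending) and then by
#' `study_id`, so the split is reproducible. The relative order of survivors
#' is preserved.
#'
#' @param pool A tibble of studies as produced by [simulate_study_pool()].
#' @param selection `"none"`, `"p_value"` or `"effect_size"`.
#' @param m_removed Number of studies to suppress; must be smaller than the
#'   pool size.
#' @param favor See [scenario_config()].
#' @return The pool tibble with an added logical column `published`.
#' @export
#' @examples
#' pool <- withr::with_seed(1, simulate_study_pool(10))
#' apply_selection(pool, "effect_size", m_removed = 3)
apply_selection <- function(pool, selection = c("none", "p_value", "effect_size"),
                            m_removed = 0L, favor = c("positive", "none")) {
  selection <- rlang::arg_match(selection)
  favor <- rlang::arg_match(favor)
  pool <- as_study_tbl(pool, min_n = 1L)
  if (m_removed < 0 || m_removed >= nrow(pool)) {
    rlang::abort("`m_removed` must satisfy 0 <= m_removed < number of studies in the pool.")
  }
  pool$published <- TRUE
  if (selection == "none" || m_removed == 0) {
    return(pool)
  }
  key <- selection_key(pool, selection, favor)
  ord <- order(-key, abs(pool$effect), pool$study_id)
  pool$published[ord[seq_len(m_removed)]] <- FALSE
  pool
}

#' Generate one simulated meta-analysis
#'
#' Runs the full data-generating process for one replicate of a simulation
#' cell: draw a pool of `n + m` studies, suppress the `m` least favourable
#' ones, and fit the random-effects model by REML to the published studies.
#' If the Fisher-scoring fit does not converge the draw is discarded and
#' regenerated (the regeneration count is recorded), so every returned
#' dataset carries a convergent fit.
#'
#' @param config A [scenario_config()].
#' @param replicate_id Replicate index within the cell; combined with
#'   `config$seed` (when set) to derive an independent random stream.
#' @param fit_fun The REML fitter; must accept a data frame with `effect`
#'   and `se` columns and return an object with a logical `converged` field.
#'   Exposed so tests can inject non-convergent fitters.
#' @param max_regen Cap on regenerations before failing with an error naming
#'   the cell.
#' @return An object of class `meta_dataset`: a list with elements
#'   `studies` (tibble with a `published` flag), `config`, `fit`,
#'   `replicate_id`, `regeneration_count`.
#' @export
#' @examples
#' cfg <- scenario_config(15, severity = 1/3, tau2 = 0,
#'                        selection = "p_value", seed = 42)
#' generate_dataset(cfg, replicate_id = 1)
generate_dataset <- function(config, replicate_id = 1L, fit_fun = reml_fit,
                             max_regen = 1000L) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) {
    withr::local_seed(cell_seed(
      config$seed,
      n = config$n_published, sev = signif(config$severity, 10),
      tau2 = config$tau2, sel = config$selection, favor = config$favor,
      rep = replicate_id
    ))
  }
  total <- config$n_published + config$m_removed
  regen <- 0L
  repeat {
    pool <- simulate_study_pool(total, mu = config$mu, tau2 = config$tau2)
    studies <- apply_selection(pool, config$selection, config$m_removed, config$favor)
    fit <- fit_fun(studies[studies$published, , drop = FALSE])
    if (isTRUE(fit$converged)) break
    regen <- regen + 1L
    if (regen > max_regen) {
      rlang::abort(sprintf(
        "REML failed to converge after %d regenerations in cell (n=%d, severity=%.3g, tau2=%.3g, selection=%s).",
        max_regen, config$n_published, config$severity, config$tau2, config$selection
      ))
    }
  }
  structure(
    list(
      studies = studies,
      config = config,
      fit = fit,
      replicate_id = as.integer(replicate_id),
      regeneration_count = regen
    ),
    class = "meta_dataset"
  )
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("<meta_dataset>\n")
  cat(sprintf("  %d published, %d unpublished studies (replicate %d, %d regeneration(s))\n",
              sum(x$studies$published), sum(!x$studies$published),
              x$replicate_id, x$regeneration_count))
  cat(sprintf("  ground truth: publication bias %s\n",
              if (truth_present(x)) "PRESENT" else "ABSENT"))
  cat(sprintf("  REML: mu_hat = %.3f (se %.3f), tau2_hat = %.3f\n",
              x$fit$mu_hat, x$fit$se_mu, x$fit$tau2_hat))
  invisible(x)
}

#' Published / unpublished studies of a simulated meta-analysis
#'
#' @param x A `meta_dataset`.
#' @return A tibble of studies.
#' @export
published_studies <- function(x) {
  stopifnot(inherits(x, "meta_dataset"))
  x$studies[x$studies$published, , drop = FALSE]
}

#' @rdname published_studies
#' @export
unpublished_studies <- function(x) {
  stopifnot(inherits(x, "meta_dataset"))
  x$studies[!x$studies$published, , drop = FALSE]
}

#' Ground-truth label of a simulated meta-analysis
#'
#' Publication bias is present by construction exactly when the cell's
#' severity is positive. Only the scoring code may look at this; detector
#' payloads never contain it.
#'
#' @param x A `meta_dataset`.
#' @return `TRUE` when studies were suppressed.
#' @export
truth_present <- function(x) {
  stopifnot(inherits(x, "meta_dataset"))
  x$config$severity > 0
}

#' Read and write study tables
#'
#' `write_studies_csv()` writes `study_id, effect, se, published` (published
#' coded 0/1). `write_studies_json()` writes the payload-style JSON twin
#' `{"studies": [{"effect_size": ..., "standard_error": ...}, ...]}` of the
#' *published* studies only. `read_studies()` reads either format (by file
#' extension) into a study tibble suitable for [reml_fit()] and the
#' publication-bias tests.
#'
#' @param x A `meta_dataset` or a data frame with `effect` and `se` columns.
#' @param path File path.
#' @return `read_studies()` returns a tibble with columns `study_id`,
#'   `effect`, `se` (and `published` when present in the file).
#' @export
write_studies_csv <- function(x, path) {
  tbl <- if (inherits(x, "meta_dataset")) x$studies else as_study_tbl(x, min_n = 1L)
  if (!"published" %in% names(tbl)) tbl$published <- TRUE
  out <- data.frame(
    study_id = tbl$study_id,
    effect = tbl$effect,
    se = tbl$se,
    published = as.integer(tbl$published)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_studies_csv
#' @export
write_studies_json <- function(x, path) {
  tbl <- if (inherits(x, "meta_dataset")) published_studies(x) else as_study_tbl(x, min_n = 1L)
  jsonlite::write_json(
    list(studies = data.frame(effect_size = tbl$effect, standard_error = tbl$se)),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_studies_csv
#' @export
read_studies <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
    studies <- parsed$studies %||% parsed
    tbl <- tibble::tibble(
      study_id = seq_len(nrow(studies)),
      effect = as.numeric(studies$effect_size %||% studies$effect),
      se = as.numeric(studies$standard_error %||% studies$se)
    )
  } else {
    raw <- utils::read.csv(path)
    tbl <- tibble::as_tibble(raw)
    if (!"study_id" %in% names(tbl)) tbl$study_id <- seq_len(nrow(tbl))
    if ("published" %in% names(tbl)) tbl$published <- tbl$published != 0
  }
  as_study_tbl(tbl, min_n = 1L)
}
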
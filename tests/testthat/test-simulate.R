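test_that("study pools have the stated support, p-values and determinism", {
  pool <- withr::with_seed(1, simulate_study_pool(10, mu = 0, tau2 = 0))
  expect_equal(nrow(pool), 10)
  expect_true(all(pool$se >= 1 & pool$se <= 4))
  expect_equal(pool$p_two_sided,
               2 * (1 - pnorm(abs(pool$effect / pool$se))),
               tolerance = 1e-12)

  again <- withr::with_seed(1, simulate_study_pool(10, mu = 0, tau2 = 0))
  expect_identical(pool, again)

  expect_error(simulate_study_pool(1), "total")
  expect_error(simulate_study_pool(10, tau2 = -1), "tau2")
})

test_that("pooled draws match the closed-form mixture moments", {
  # Var(y) = E[s^2] + tau2; E[s^2] = (4^3 - 1^3) / (3 * (4 - 1)) = 7
  pool <- withr::with_seed(99, simulate_study_pool(10000, mu = 0, tau2 = 0))
  expect_lt(abs(mean(pool$effect)), 4 * sqrt(7 / 10000))
  expect_lt(abs(var(pool$effect) - 7) / 7, 0.05)

  het <- withr::with_seed(100, simulate_study_pool(10000, mu = 0, tau2 = 1))
  expect_lt(abs(var(het$effect) - 8) / 8, 0.05)
})

test_that("under the null the significant fraction is nominal", {
  pool <- withr::with_seed(7, simulate_study_pool(20000, mu = 0, tau2 = 0))
  frac <- mean(pool$p_two_sided < 0.05)
  ci <- 0.05 + c(-4, 4) * sqrt(0.05 * 0.95 / 20000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("selection removes the studies the ranking rule dictates", {
  pool <- tibble::tibble(
    study_id = 1:3,
    effect = c(2.5, 0.1, 1.5),
    se = c(1, 1.5, 2)
  )
  pool$p_two_sided <- 2 * pnorm(-abs(pool$effect / pool$se))

  # identity case
  out <- apply_selection(pool, "none", 0)
  expect_true(all(out$published))

  # symmetric variant: largest two-sided p suppressed
  p_pool <- pool
  p_pool$effect <- c(3.5, 0.15, 0.25) # two-sided p ~ (0.0005, 0.92, 0.90)
  p_pool$p_two_sided <- 2 * pnorm(-abs(p_pool$effect / p_pool$se))
  out <- apply_selection(p_pool, "p_value", 1, favor = "none")
  expect_identical(out$study_id[!out$published], 2L)

  # symmetric variant: smallest |effect| suppressed
  e_pool <- pool
  e_pool$effect <- c(-2.0, 0.1, 1.5)
  out <- apply_selection(e_pool, "effect_size", 1, favor = "none")
  expect_identical(out$study_id[!out$published], 2L)

  # directional default: least favourable = most negative effect
  out <- apply_selection(e_pool, "effect_size", 1, favor = "positive")
  expect_identical(out$study_id[!out$published], 1L)

  # directional default: least favourable = largest one-sided p
  d_pool <- pool
  d_pool$effect <- c(2.5, -0.1, 1.5) # one-sided p largest for study 2
  d_pool$p_two_sided <- 2 * pnorm(-abs(d_pool$effect / d_pool$se))
  out <- apply_selection(d_pool, "p_value", 1, favor = "positive")
  expect_identical(out$study_id[!out$published], 2L)

  expect_error(apply_selection(pool, "p_value", 3), "m_removed")
})

test_that("selection rankings dominate between published and unpublished", {
  for (seed in 1:20) {
    pool <- withr::with_seed(seed, simulate_study_pool(20, tau2 = seed %% 2))

    out <- apply_selection(pool, "p_value", 6, favor = "none")
    expect_gte(min(out$p_two_sided[!out$published]),
               max(out$p_two_sided[out$published]))

    out <- apply_selection(pool, "effect_size", 6, favor = "none")
    expect_lte(max(abs(out$effect[!out$published])),
               min(abs(out$effect[out$published])))

    out <- apply_selection(pool, "effect_size", 6, favor = "positive")
    expect_lte(max(out$effect[!out$published]),
               min(out$effect[out$published]))

    out <- apply_selection(pool, "p_value", 6, favor = "positive")
    key <- 1 - pnorm(out$effect / out$se)
    expect_gte(min(key[!out$published]), max(key[out$published]))
  }
})

test_that("suppressed-study counts follow half-up rounding of severity * n", {
  m_of <- function(n, sev, sel = "p_value", ...) {
    scenario_config(n, severity = sev,
                    selection = if (sev == 0) "none" else sel, ...)$m_removed
  }
  expect_identical(sapply(c(0, 1 / 10, 1 / 5, 1 / 3), function(s) m_of(15, s)),
                   c(0L, 2L, 3L, 5L))
  expect_identical(m_of(30, 1 / 10), 3L)
  expect_identical(m_of(75, 1 / 3), 25L)
  expect_identical(m_of(15, 1 / 10, rounding = "floor"), 1L)

  expect_error(scenario_config(15, severity = 0, selection = "p_value"),
               "if and only if")
  expect_error(scenario_config(15, severity = 0.2, selection = "none"),
               "if and only if")
  expect_error(scenario_config(5, severity = 0.01, selection = "p_value"),
               "at least one study")
})

test_that("generated datasets have exactly n published studies and a convergent fit", {
  ds <- make_dataset(n = 15, severity = 1 / 3)
  expect_s3_class(ds, "meta_dataset")
  expect_equal(nrow(published_studies(ds)), 15)
  expect_equal(nrow(unpublished_studies(ds)), 5)
  expect_true(truth_present(ds))
  expect_true(ds$fit$converged)

  null_ds <- make_dataset(n = 30, severity = 0, selection = "none")
  expect_equal(nrow(published_studies(null_ds)), 30)
  expect_equal(nrow(unpublished_studies(null_ds)), 0)
  expect_false(truth_present(null_ds))

  # identical stream -> identical dataset
  again <- make_dataset(n = 15, severity = 1 / 3)
  expect_identical(ds$studies, again$studies)
})

test_that("non-convergent fits trigger regeneration without touching the config", {
  cfg <- scenario_config(10, severity = 1 / 5, selection = "p_value", seed = 3)
  fails_left <- 3L
  flaky_fit <- function(data) {
    fit <- reml_fit(data)
    if (fails_left > 0L) {
      fails_left <<- fails_left - 1L
      fit$converged <- FALSE
    }
    fit
  }
  ds <- generate_dataset(cfg, replicate_id = 2, fit_fun = flaky_fit)
  expect_equal(ds$regeneration_count, 3L)
  expect_identical(ds$config, cfg)
  expect_equal(ds$replicate_id, 2L)
  expect_true(ds$fit$converged)

  never <- function(data) list(converged = FALSE)
  expect_error(generate_dataset(cfg, fit_fun = never, max_regen = 5),
               "regenerations")
})

test_that("study tables round-trip through CSV and JSON", {
  ds <- make_dataset(n = 10, severity = 1 / 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")

  write_studies_csv(ds, csv)
  back <- read_studies(csv)
  expect_equal(back$effect, ds$studies$effect, tolerance = 1e-12)
  expect_equal(back$se, ds$studies$se, tolerance = 1e-12)
  expect_equal(back$published, ds$studies$published)

  write_studies_json(ds, json)
  pub <- read_studies(json)
  expect_equal(pub$effect, published_studies(ds)$effect, tolerance = 1e-12)
  expect_equal(pub$se, published_studies(ds)$se, tolerance = 1e-12)
  # JSON twin carries only the published studies
  expect_equal(nrow(pub), 10)
})

test_that("cell seeds are stable, distinct and in range", {
  a <- cell_seed(1, "n=15", rep = 1)
  expect_identical(a, cell_seed(1, "n=15", rep = 1))
  expect_false(a == cell_seed(1, "n=15", rep = 2))
  expect_false(a == cell_seed(2, "n=15", rep = 1))
  seeds <- vapply(1:500, function(i) cell_seed(1, "x", i), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 2))
  expect_gt(length(unique(seeds)), 495) # collisions essentially absent
})
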
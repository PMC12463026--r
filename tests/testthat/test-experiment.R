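small_spec <- function(...) {
  grid_spec(n_list = c(10, 15), severities = c(0, 1 / 5, 1 / 3),
            tau2_list = 0, scenarios = "p_value", replicates = 4, seed = 7, ...)
}

test_that("the default grid enumerates the benchmark cells", {
  spec <- grid_spec()
  cells <- grid_cells(spec)
  # per n: 2 tau2 x (3 severities x 2 scenarios) PB cells + 2 collapsed nulls
  expect_equal(nrow(cells), 4 * (2 * 6 + 2))
  expect_equal(sort(unique(cells$n)), c(15L, 30L, 50L, 75L))
  null_cells <- cells[cells$severity == 0, ]
  expect_true(all(null_cells$selection == "none"))
  expect_equal(nrow(null_cells), 8)

  m15 <- sapply(split(cells, seq_len(nrow(cells))), function(cell) {
    if (cell$n != 15) return(NA_integer_)
    biasbench:::cell_config(spec, cell)$m_removed
  })
  expect_equal(sort(unique(na.omit(m15))), c(0L, 2L, 3L, 5L))
})

test_that("constant detectors force the degenerate metric corners", {
  spec <- small_spec()
  res <- run_grid(spec, list(detector_always("present"), detector_always("absent")))
  m <- summarize_metrics(res, detector, ci = FALSE)

  m_present <- m[m$detector == "always-present", ]
  expect_equal(m_present$sensitivity, 1)
  expect_equal(m_present$specificity, 0)

  m_absent <- m[m$detector == "always-absent", ]
  expect_equal(m_absent$sensitivity, 0)
  expect_equal(m_absent$specificity, 1)
})

test_that("the oracle detector attains consistency 1 in every cell", {
  spec <- small_spec()
  res <- run_grid(spec, detector_oracle())
  per_cell <- summarize_metrics(res, n, severity, selection, ci = FALSE)
  expect_true(all(per_cell$consistency == 1))
})

test_that("grid runs are deterministic and schedule-invariant", {
  spec <- small_spec()
  r1 <- run_grid(spec, list(detector_oracle(), detector_egger()),
                 input_modes = "combined")
  r2 <- run_grid(spec, list(detector_egger(), detector_oracle()),
                 input_modes = "combined")
  key <- c("n", "severity", "selection", "replicate", "detector")
  d1 <- dplyr::arrange(r1$decisions, dplyr::across(dplyr::all_of(key)))
  d2 <- dplyr::arrange(r2$decisions, dplyr::across(dplyr::all_of(key)))
  expect_identical(d1$verdict, d2$verdict)
  expect_identical(d1$score, d2$score)
})

test_that("every cell ends with exactly `replicates` convergent datasets", {
  spec <- small_spec()
  res <- run_grid(spec, detector_oracle())
  tally <- res$decisions |>
    dplyr::group_by(n, tau2, severity, selection) |>
    dplyr::summarise(datasets = dplyr::n(), .groups = "drop")
  expect_equal(nrow(tally), nrow(grid_cells(spec)))
  expect_true(all(tally$datasets == spec$replicates))
})

test_that("the Egger detector in the pipeline matches the direct benchmark", {
  spec <- small_spec()
  res <- run_grid(spec, detector_egger(), input_modes = "combined")
  bench <- benchmark_traditional(spec)
  egger_flags <- bench$results[bench$results$method == "egger", ]
  key <- c("n", "tau2", "severity", "selection", "replicate")
  merged <- dplyr::inner_join(res$decisions, egger_flags, by = key)
  expect_equal(nrow(merged), nrow(res$decisions))
  expect_equal(merged$verdict == "present", merged$flagged)
})

test_that("benchmark reports pool rejection rates with recorded denominators", {
  spec <- small_spec()
  bench <- benchmark_traditional(spec)
  report <- bench$report
  expect_setequal(unique(report$method), c("egger", "begg", "trim_fill", "pooled"))
  n10 <- report[report$n == 10 & report$method == "pooled", ]
  expect_equal(n10$n_null, 3 * 4) # 1 null cell x 4 replicates x 3 methods
  expect_equal(n10$n_pb, 2 * 4 * 3)
  per_method <- report[report$n == 10 & report$method != "pooled", ]
  expect_equal(mean(per_method$power), n10$power, tolerance = 1e-12)
  expect_true(all(na.omit(c(report$power, report$type1)) >= 0 &
                    na.omit(c(report$power, report$type1)) <= 1))
})

test_that("box summaries reproduce order-statistic quartiles and whiskers", {
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 12),
    v = c(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 100), rep(0.5, 12))
  )
  out <- summarize_boxplots(d, v, g)
  sa <- out$stats[out$stats$g == "a", ]
  expect_equal(sa$q1, quantile(d$v[d$g == "a"], 0.25, names = FALSE))
  expect_equal(sa$median, 6.5)
  expect_equal(sa$q3, quantile(d$v[d$g == "a"], 0.75, names = FALSE))
  # the outlier at 100 lies beyond q3 + 1.5 IQR and is excluded
  iqr <- sa$q3 - sa$q1
  expect_lte(sa$whisker_hi, sa$q3 + 1.5 * iqr)
  expect_equal(sa$whisker_hi, 11)
  expect_equal(sa$n_outliers, 1)

  # degenerate box: constant values collapse everything
  sb <- out$stats[out$stats$g == "b", ]
  expect_equal(sb$q1, 0.5)
  expect_equal(sb$median, 0.5)
  expect_equal(sb$q3, 0.5)
  expect_equal(sb$whisker_lo, 0.5)
  expect_equal(sb$whisker_hi, 0.5)
  expect_s3_class(out$plot, "ggplot")

  csv <- withr::local_tempfile(fileext = ".csv")
  summarize_boxplots(d, v, g, csv_path = csv)
  expect_true(file.exists(csv))
})

test_that("the case-study workflow flags the synthetic biased meta-analysis", {
  path <- system.file("extdata", "synthetic_smd_case_study.csv",
                      package = "biasbench")
  cs <- case_study(path)
  expect_s3_class(cs$fit, "reml_fit")
  expect_true(cs$fit$converged)
  expect_equal(nrow(cs$tests), 3)
  expect_true(cs$tests$flagged[cs$tests$method == "egger"])
  expect_lt(cs$tests$p_value[cs$tests$method == "egger"], 0.001)
  expect_s3_class(cs$plot, "ggplot")
})

test_that("grid specifications round-trip through YAML", {
  spec <- grid_spec(n_list = c(15, 30), severities = c(0, 1 / 3),
                    tau2_list = c(0, 1), scenarios = "effect_size",
                    replicates = 10, seed = 123, favor = "positive")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_grid_spec(spec, path)
  back <- read_grid_spec(path)
  expect_equal(back$n_list, spec$n_list)
  expect_equal(back$severities, spec$severities)
  expect_equal(back$scenarios, spec$scenarios)
  expect_equal(back$seed, spec$seed)
})

test_that("transcripts are written as one JSON line per run", {
  spec <- grid_spec(n_list = 10, severities = c(0, 1 / 5),
                    tau2_list = 0, scenarios = "p_value",
                    replicates = 2, seed = 1)
  res <- run_grid(spec, detector_scripted(c("Present", "Absent")),
                  keep_runs = TRUE, repeats = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcripts(res$decisions, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(res$decisions) * 5)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("replicate", "detector", "verdict", "run_index",
                    "response", "parsed") %in% names(rec)))
})
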
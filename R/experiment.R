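#' Define a simulation grid
#'
#' The full factorial benchmark design: numbers of published studies,
#' suppression severities, between-study variances and selection scenarios,
#' each cell replicated independently. Severity-0 cells are generated once
#' per (n, tau2) and shared across scenario labels, since selection is a
#' no-op there.
#'
#' @param n_list Numbers of published studies (default 15, 30, 50, 75).
#' @param severities Suppressed-to-published ratios m/n (default 0, 1/10,
#'   1/5, 1/3).
#' @param tau2_list Between-study variances (default 0 and 1).
#' @param scenarios Selection mechanisms applied in the severity > 0 cells.
#' @param replicates Meta-analyses per cell (default 100).
#' @param seed Root seed; every (cell, replicate) derives its own stream via
#'   [cell_seed()], so results do not depend on evaluation order.
#' @param alpha Two-sided significance level.
#' @param favor Suppression direction, see [scenario_config()].
#' @param mu True overall effect.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(n_list = 15, replicates = 5, seed = 1)
grid_spec <- function(n_list = c(15, 30, 50, 75),
                      severities = c(0, 1 / 10, 1 / 5, 1 / 3),
                      tau2_list = c(0, 1),
                      scenarios = c("p_value", "effect_size"),
                      replicates = 100L,
                      seed = 1L,
                      alpha = 0.05,
                      favor = c("positive", "none"),
                      mu = 0) {
  favor <- rlang::arg_match(favor)
  scenarios <- match.arg(scenarios, c("p_value", "effect_size"), several.ok = TRUE)
  stopifnot(all(n_list >= 2), all(severities >= 0), all(tau2_list >= 0),
            replicates >= 1)
  structure(
    list(
      n_list = as.integer(n_list),
      severities = severities,
      tau2_list = tau2_list,
      scenarios = scenarios,
      replicates = as.integer(replicates),
      seed = as.integer(seed),
      alpha = alpha,
      favor = favor,
      mu = mu
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cells <- grid_cells(x)
  cat("<grid_spec>\n")
  cat(sprintf("  n: {%s}, severities: {%s}, tau2: {%s}\n",
              paste(x$n_list, collapse = ", "),
              paste(signif(x$severities, 3), collapse = ", "),
              paste(x$tau2_list, collapse = ", ")))
  cat(sprintf("  scenarios: %s (favor = %s)\n",
              paste(x$scenarios, collapse = ", "), x$favor))
  cat(sprintf("  %d cells x %d replicates = %d datasets (seed %d)\n",
              nrow(cells), x$replicates, nrow(cells) * x$replicates, x$seed))
  invisible(x)
}

#' Enumerate the cells of a grid
#'
#' @param spec A `grid_spec`.
#' @return A tibble with one row per cell: `n`, `tau2`, `severity`,
#'   `selection` (`"none"` in the collapsed severity-0 cells).
#' @export
grid_cells <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  pb <- tidyr::expand_grid(
    n = spec$n_list,
    tau2 = spec$tau2_list,
    severity = spec$severities[spec$severities > 0],
    selection = spec$scenarios
  )
  out <- pb
  if (any(spec$severities == 0)) {
    null_cells <- tidyr::expand_grid(
      n = spec$n_list,
      tau2 = spec$tau2_list,
      severity = 0,
      selection = "none"
    )
    out <- dplyr::bind_rows(null_cells, pb)
  }
  dplyr::arrange(out, .data$n, .data$tau2, .data$severity, .data$selection)
}

# scenario_config for one cell row of a grid
cell_config <- function(spec, cell) {
  scenario_config(
    n_published = cell$n,
    severity = cell$severity,
    tau2 = cell$tau2,
    selection = cell$selection,
    mu = spec$mu,
    alpha = spec$alpha,
    seed = spec$seed,
    favor = spec$favor
  )
}

#' Evaluate detectors over a simulation grid
#'
#' For every cell and replicate: generate the dataset (regenerating on REML
#' non-convergence), build the detector payload for each input mode, query
#' each detector under the five-run agreement rule, and score the verdict
#' against the ground truth. The whole run is reproducible from
#' `(spec, spec$seed)`; datasets are generated per (cell, replicate) stream,
#' so the decision log does not depend on which detectors are attached.
#'
#' @param spec A `grid_spec`.
#' @param detectors A `pb_detector` or list of them.
#' @param input_modes `"visual"`, `"combined"`, or both. Statistical
#'   detectors need `"combined"` (they read the study table).
#' @param render Render funnel PNGs into the payloads. Defaults to `FALSE`:
#'   the built-in statistical and mock detectors never look at the raster,
#'   and skipping it keeps large grids fast. Set `TRUE` when querying
#'   multimodal detectors.
#' @param keep_runs Keep the verbatim per-run transcripts as a list-column
#'   (needed by [write_transcripts()]).
#' @param repeats Override the per-detector query count (default: 1 for
#'   deterministic detectors, 5 otherwise).
#' @return An object of class `pb_grid_result`: list with `decisions` (one
#'   row per cell x replicate x detector x mode, with `verdict`, `score`
#'   and `regenerations`) and `spec`.
#' @export
#' @examples
#' spec <- grid_spec(n_list = 15, tau2_list = 0, scenarios = "p_value",
#'                   replicates = 3, seed = 1)
#' run_grid(spec, detector_always("present"))
run_grid <- function(spec, detectors, input_modes = "visual", render = FALSE,
                     keep_runs = FALSE, repeats = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (inherits(detectors, "pb_detector")) detectors <- list(detectors)
  stopifnot(length(detectors) >= 1,
            all(vapply(detectors, inherits, logical(1), "pb_detector")))
  input_modes <- match.arg(input_modes, c("visual", "combined"), several.ok = TRUE)
  cells <- grid_cells(spec)
  rows <- vector("list", nrow(cells) * spec$replicates * length(detectors) * length(input_modes))
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    config <- cell_config(spec, cell)
    for (rep_id in seq_len(spec$replicates)) {
      ds <- generate_dataset(config, replicate_id = rep_id)
      truth <- truth_present(ds)
      for (mode in input_modes) {
        payload <- payload_for_llm(ds, include_data = (mode == "combined"),
                                   render = render)
        bundle <- build_prompt(mode, payload)
        for (det in detectors) {
          decision <- decide_with_agreement(det, bundle, repeats = repeats,
                                            truth = truth)
          idx <- idx + 1L
          rows[[idx]] <- tibble::tibble(
            n = cell$n, tau2 = cell$tau2, severity = cell$severity,
            selection = cell$selection, replicate = rep_id,
            detector = det$id, mode = mode,
            verdict = decision$verdict,
            truth = truth,
            score = score_decision(decision$verdict, truth),
            regenerations = ds$regeneration_count,
            runs = if (keep_runs) list(decision$runs) else list(NULL)
          )
        }
      }
    }
  }
  decisions <- dplyr::bind_rows(rows)
  if (!keep_runs) decisions$runs <- NULL
  structure(list(decisions = decisions, spec = spec), class = "pb_grid_result")
}

#' @export
print.pb_grid_result <- function(x, ...) {
  cat("<pb_grid_result>\n")
  cat(sprintf("  %d decisions (%d detector(s), modes: %s)\n",
              nrow(x$decisions), length(unique(x$decisions$detector)),
              paste(unique(x$decisions$mode), collapse = ", ")))
  print(summarize_metrics(x, .data$detector, .data$mode), ...)
  invisible(x)
}

#' Aggregate a decision log into the metric suite
#'
#' Groups the decision log (by detector, input mode, cell margins, ...) and
#' computes the confusion-matrix metrics per group, together with
#' replication percentile confidence intervals: for each metric, the
#' replicate-level value is computed from the decisions of that replicate
#' index within the group, and [replication_ci()] summarises the spread of
#' those values.
#'
#' @param x A `pb_grid_result` or its decision-log tibble.
#' @param ... Grouping columns (data-masked), e.g. `detector, n`.
#' @param ci Attach replication confidence intervals (columns
#'   `<metric>_low`, `<metric>_high`).
#' @param level CI coverage.
#' @return A tibble with one row per group.
#' @export
#' @examples
#' spec <- grid_spec(n_list = 15, tau2_list = 0, scenarios = "p_value",
#'                   replicates = 4, seed = 1)
#' res <- run_grid(spec, detector_always("present"))
#' summarize_metrics(res, detector)
summarize_metrics <- function(x, ..., ci = TRUE, level = 0.95) {
  decisions <- if (inherits(x, "pb_grid_result")) x$decisions else x
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "f1", "consistency")
  grouped <- dplyr::group_by(decisions, ...)
  out <- dplyr::group_modify(grouped, function(d, key) {
    m <- compute_metrics(confusion_counts(d$score))
    if (ci && length(unique(d$replicate)) >= 2) {
      per_rep <- lapply(split(d, d$replicate), function(dr) {
        compute_metrics(confusion_counts(dr$score))
      })
      per_rep <- dplyr::bind_rows(per_rep)
      for (mn in metric_names) {
        vals <- per_rep[[mn]]
        if (sum(!is.na(vals)) >= 2) {
          interval <- replication_ci(vals, level = level)
          m[[paste0(mn, "_low")]] <- interval[["low"]]
          m[[paste0(mn, "_high")]] <- interval[["high"]]
        } else {
          m[[paste0(mn, "_low")]] <- NA_real_
          m[[paste0(mn, "_high")]] <- NA_real_
        }
      }
    }
    m
  })
  dplyr::ungroup(out)
}

#' Benchmark the traditional tests over a simulation grid
#'
#' Runs Egger's regression, Begg's rank correlation and trim-and-fill on
#' every generated dataset of the grid (no detectors, no rendering) and
#' summarises rejection rates: the type-I error of each method from the
#' severity-0 cells and its power pooled across the bias-present cells,
#' per number of studies. `"pooled"` rows average the three methods — the
#' single-number-per-n summary used by the power benchmark.
#'
#' Datasets are generated from the same per-(cell, replicate) streams as
#' [run_grid()], so an Egger-backed detector run through the full pipeline
#' reproduces exactly the Egger flags found here.
#'
#' @param spec A `grid_spec`.
#' @param continuity Continuity correction for Begg's test.
#' @return An object of class `pb_benchmark`: list with `results` (one row
#'   per dataset x method) and `report` (per (n, method): `type1`, `power`,
#'   `n_null`, `n_pb` denominators).
#' @export
#' @examples
#' spec <- grid_spec(n_list = 15, tau2_list = 0, scenarios = "p_value",
#'                   replicates = 3, seed = 1)
#' benchmark_traditional(spec)
benchmark_traditional <- function(spec, continuity = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- grid_cells(spec)
  rows <- vector("list", nrow(cells) * spec$replicates)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    config <- cell_config(spec, cell)
    for (rep_id in seq_len(spec$replicates)) {
      ds <- generate_dataset(config, replicate_id = rep_id)
      tests <- pb_test_all(published_studies(ds), alpha = spec$alpha,
                           continuity = continuity)
      idx <- idx + 1L
      rows[[idx]] <- dplyr::mutate(
        tests,
        n = cell$n, tau2 = cell$tau2, severity = cell$severity,
        selection = cell$selection, replicate = rep_id,
        regenerations = ds$regeneration_count,
        .before = 1
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  per_method <- results |>
    dplyr::group_by(.data$n, .data$method) |>
    dplyr::summarise(
      type1 = if (any(.data$severity == 0)) {
        mean(.data$flagged[.data$severity == 0])
      } else NA_real_,
      power = if (any(.data$severity > 0)) {
        mean(.data$flagged[.data$severity > 0])
      } else NA_real_,
      n_null = sum(.data$severity == 0),
      n_pb = sum(.data$severity > 0),
      .groups = "drop"
    )
  pooled <- results |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      method = "pooled",
      type1 = if (any(.data$severity == 0)) {
        mean(.data$flagged[.data$severity == 0])
      } else NA_real_,
      power = if (any(.data$severity > 0)) {
        mean(.data$flagged[.data$severity > 0])
      } else NA_real_,
      n_null = sum(.data$severity == 0),
      n_pb = sum(.data$severity > 0),
      .groups = "drop"
    )
  report <- dplyr::arrange(dplyr::bind_rows(per_method, pooled),
                           .data$n, .data$method)
  structure(list(results = results, report = report, spec = spec),
            class = "pb_benchmark")
}

#' @export
print.pb_benchmark <- function(x, ...) {
  cat("<pb_benchmark> rejection rates of the traditional tests\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' @rdname benchmark_traditional
#' @param object A `pb_benchmark` (autoplot interface).
#' @param ... Unused.
#' @method autoplot pb_benchmark
#' @export
autoplot.pb_benchmark <- function(object, ...) {
  report <- tidyr::pivot_longer(object$report, c("type1", "power"),
                                names_to = "quantity", values_to = "rate")
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$n, y = .data$rate,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = "Published studies per meta-analysis",
                  y = "Rejection rate", colour = "Method") +
    ggplot2::theme_bw()
}

#' Box-and-whisker summary of replicate-level values
#'
#' Computes, per group, the quartiles, the whisker ends (the most extreme
#' values within 1.5 x IQR of the quartile) and the outliers beyond them,
#' and draws the matching box plot from those precomputed statistics. A
#' tidy CSV of the quartiles can be written alongside.
#'
#' @param data A tibble of replicate-level values (e.g. per-replicate
#'   consistency from [summarize_metrics()] groups, or a decision log
#'   aggregated per replicate).
#' @param value Column of values to summarise (data-masked).
#' @param ... Grouping columns (data-masked); the first is mapped to the
#'   plot's x axis, a column named `n` (if among them) is faceted.
#' @param csv_path Optional path for the tidy quartile CSV.
#' @return A list with `stats` (tibble: group columns, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`, `n_values`) and
#'   `plot` (ggplot built from the stats).
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 20),
#'                     v = c(rnorm(20), rnorm(20, 1)))
#' summarize_boxplots(d, v, g)$stats
summarize_boxplots <- function(data, value, ..., csv_path = NULL) {
  value <- rlang::enquo(value)
  group_quos <- rlang::enquos(...)
  if (length(group_quos) == 0) rlang::abort("Give at least one grouping column.")
  stats <- data |>
    dplyr::group_by(!!!group_quos) |>
    dplyr::summarise(
      q1 = stats::quantile(!!value, 0.25, type = 7, names = FALSE),
      median = stats::median(!!value),
      q3 = stats::quantile(!!value, 0.75, type = 7, names = FALSE),
      whisker_lo = {
        v <- !!value
        iqr <- .data$q3 - .data$q1
        min(v[v >= .data$q1 - 1.5 * iqr])
      },
      whisker_hi = {
        v <- !!value
        iqr <- .data$q3 - .data$q1
        max(v[v <= .data$q3 + 1.5 * iqr])
      },
      n_outliers = {
        v <- !!value
        iqr <- .data$q3 - .data$q1
        sum(v < .data$q1 - 1.5 * iqr | v > .data$q3 + 1.5 * iqr)
      },
      n_values = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(csv_path)) {
    utils::write.csv(stats, csv_path, row.names = FALSE)
  }
  x_name <- rlang::as_name(group_quos[[1]])
  plot <- ggplot2::ggplot(stats,
                          ggplot2::aes(x = factor(.data[[x_name]]))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", width = 0.6, fill = "grey90"
    ) +
    ggplot2::labs(x = x_name, y = "Value") +
    ggplot2::theme_bw()
  if ("n" %in% vapply(group_quos, rlang::as_name, character(1)) && x_name != "n") {
    plot <- plot + ggplot2::facet_wrap(~n, labeller = ggplot2::label_both)
  }
  list(stats = stats, plot = plot)
}

#' Analyse a user-supplied meta-analysis for publication bias
#'
#' The case-study workflow: read a study table (CSV with `effect`/`se`
#' columns or payload-style JSON), fit the random-effects model by REML,
#' run all three traditional tests, and prepare the funnel plot. No data
#' ship with the package; the fixture used in the examples is synthetic.
#'
#' @param path Path to the study table, or a data frame.
#' @param alpha Two-sided significance level.
#' @return An object of class `pb_case_study`: list with `studies`, `fit`
#'   (`reml_fit`), `tests` (tidy tibble) and `plot` (ggplot funnel).
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_smd_case_study.csv",
#'                     package = "biasbench")
#' case_study(path)
case_study <- function(path, alpha = 0.05) {
  studies <- if (is.data.frame(path)) as_study_tbl(path) else read_studies(path)
  if ("published" %in% names(studies)) {
    studies <- studies[studies$published, , drop = FALSE]
  }
  fit <- reml_fit(studies)
  structure(
    list(
      studies = studies,
      fit = fit,
      tests = pb_test_all(studies, alpha = alpha),
      plot = funnel_plot(studies, mu_hat = fit$mu_hat)
    ),
    class = "pb_case_study"
  )
}

#' @export
print.pb_case_study <- function(x, ...) {
  cat(sprintf("<pb_case_study> %d studies\n", nrow(x$studies)))
  print(x$fit)
  print(x$tests)
  invisible(x)
}

#' Read and write a grid specification as YAML
#'
#' @param spec A `grid_spec`.
#' @param path YAML file path.
#' @return `read_grid_spec()` returns a `grid_spec`.
#' @export
write_grid_spec <- function(spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(grid_spec, raw[c("n_list", "severities", "tau2_list", "scenarios",
                           "replicates", "seed", "alpha", "favor", "mu")])
}
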
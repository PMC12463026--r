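#' Funnel plot of a meta-analysis
#'
#' Scatter of effect size (x) against standard error (y) with the y axis
#' inverted so the most precise studies sit at the top, a vertical reference
#' line at the REML pooled estimate, and a white background. One point is
#' drawn per published study. The x axis is symmetric about the pooled
#' estimate and covers all points with a 5% margin; the y axis runs from 0
#' to `max(se) * 1.05`. Optionally a 95% pseudo-confidence wedge
#' \eqn{\hat\mu \pm 1.96 s} is drawn (off by default).
#'
#' @param x A `meta_dataset` or a data frame with `effect` and `se` columns
#'   (all rows are treated as published).
#' @param pseudo_ci Draw the 95% pseudo-confidence wedge.
#' @param mu_hat Optional pooled estimate to centre on; defaults to the
#'   dataset's REML fit (or a fresh REML fit for a plain data frame).
#' @return A ggplot object.
#' @export
#' @examples
#' cfg <- scenario_config(30, severity = 1/3, tau2 = 0,
#'                        selection = "effect_size", seed = 1)
#' funnel_plot(generate_dataset(cfg))
funnel_plot <- function(x, pseudo_ci = FALSE, mu_hat = NULL) {
  if (inherits(x, "meta_dataset")) {
    tbl <- published_studies(x)
    mu_hat <- mu_hat %||% x$fit$mu_hat
  } else {
    tbl <- as_study_tbl(x)
    mu_hat <- mu_hat %||% reml_fit(tbl)$mu_hat
  }
  if (nrow(tbl) < 2) rlang::abort("A funnel plot needs at least 2 studies.")
  y_max <- max(tbl$se) * 1.05
  half <- max(abs(tbl$effect - mu_hat)) * 1.05
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$effect, y = .data$se))
  if (pseudo_ci) {
    wedge <- pseudo_ci_band(mu_hat, se_max = y_max)
    p <- p + ggplot2::geom_polygon(
      data = wedge, ggplot2::aes(x = .data$effect, y = .data$se),
      fill = "grey85", colour = NA
    )
  }
  p +
    ggplot2::geom_vline(xintercept = mu_hat, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(shape = 21, fill = "white", colour = "black", size = 2) +
    ggplot2::scale_y_reverse(limits = c(y_max, 0), expand = c(0, 0)) +
    ggplot2::coord_cartesian(xlim = c(mu_hat - half, mu_hat + half)) +
    ggplot2::labs(x = "Effect size", y = "Standard error") +
    ggplot2::theme_bw(base_size = 12) +
    ggplot2::theme(
      panel.grid.minor = ggplot2::element_blank(),
      plot.background = ggplot2::element_rect(fill = "white", colour = NA)
    )
}

#' @rdname funnel_plot
#' @param object A `meta_dataset` (autoplot interface).
#' @param ... Passed to [funnel_plot()].
#' @method autoplot meta_dataset
#' @export
autoplot.meta_dataset <- function(object, ...) {
  funnel_plot(object, ...)
}

# 95% pseudo-confidence wedge about mu, as a closed polygon over the se axis.
pseudo_ci_band <- function(mu_hat, se_max, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se_grid <- seq(0, se_max, length.out = 50)
  tibble::tibble(
    effect = c(mu_hat - zq * se_grid, rev(mu_hat + zq * se_grid)),
    se = c(se_grid, rev(se_grid))
  )
}

#' Render a funnel plot to a reproducible PNG payload
#'
#' Renders the funnel plot of a dataset to an exactly 600 x 600 pixel PNG
#' (the raster size consumed by the multimodal detectors), reads the bytes
#' back, and base64-encodes them. Rendering is deterministic: identical
#' datasets and style yield byte-identical PNGs.
#'
#' @param dataset A `meta_dataset` (or study data frame).
#' @param path Optional path to keep the PNG at; defaults to a temp file
#'   that is removed after reading.
#' @param width,height Raster size in pixels.
#' @param pseudo_ci Passed to [funnel_plot()].
#' @return An object of class `funnel_image`: list with `png` (raw bytes),
#'   `base64`, `width`, `height`, `dataset_ref` and `coords` (tibble of the
#'   plotted point coordinates, exposed for testing).
#' @export
render_funnel <- function(dataset, path = NULL, width = 600, height = 600,
                          pseudo_ci = FALSE) {
  p <- funnel_plot(dataset, pseudo_ci = pseudo_ci)
  file <- path %||% tempfile(fileext = ".png")
  ragg::agg_png(file, width = width, height = height, units = "px",
                background = "white")
  ok <- FALSE
  tryCatch({
    print(p)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) rlang::abort("Funnel rendering failed.")
  bytes <- readBin(file, "raw", n = file.info(file)$size)
  if (is.null(path)) unlink(file)
  built <- ggplot2::ggplot_build(p)
  point_layer <- which(vapply(p$layers, function(l) inherits(l$geom, "GeomPoint"), logical(1)))
  coords <- tibble::as_tibble(built$data[[point_layer[1]]][, c("x", "y")])
  dims <- png_dims(bytes)
  structure(
    list(
      png = bytes,
      base64 = jsonlite::base64_enc(bytes),
      width = dims[["width"]],
      height = dims[["height"]],
      dataset_ref = dataset_ref(dataset),
      coords = coords
    ),
    class = "funnel_image"
  )
}

#' @export
print.funnel_image <- function(x, ...) {
  cat(sprintf("<funnel_image> %dx%d PNG, %d bytes (ref: %s)\n",
              x$width, x$height, length(x$png), x$dataset_ref))
  invisible(x)
}

#' Read the dimensions of a PNG from its bytes
#'
#' Parses the IHDR chunk (bytes 17-24) of an in-memory PNG.
#'
#' @param bytes Raw vector of PNG bytes.
#' @return Named integer vector `c(width = , height = )`.
#' @export
png_dims <- function(bytes) {
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 24 || !identical(bytes[1:8], sig)) {
    rlang::abort("Not a PNG byte stream.")
  }
  be <- function(b) sum(as.integer(b) * 256^(3:0))
  c(width = be(bytes[17:20]), height = be(bytes[21:24]))
}

dataset_ref <- function(dataset) {
  if (inherits(dataset, "meta_dataset")) {
    sprintf("dataset-r%d-k%d", dataset$replicate_id, sum(dataset$studies$published))
  } else {
    sprintf("dataset-k%d", nrow(dataset))
  }
}

#' Build the detector-facing payload for a dataset
#'
#' Packages what a detector is allowed to see: the base64-encoded funnel
#' plot and, when `include_data` is `TRUE`, the JSON-style study table of
#' published effect sizes and standard errors. Nothing else crosses this
#' boundary — in particular the unpublished studies, the severity and the
#' ground-truth label are unreachable from the payload.
#'
#' @param dataset A `meta_dataset`.
#' @param include_data Attach the study table (the "combined input" mode).
#' @param render Render the PNG (default). `render = FALSE` skips the raster
#'   for purely statistical or scripted detectors that never look at it; the
#'   payload then carries an empty image slot.
#' @return An object of class `llm_payload`: list with `image_base64`,
#'   `studies` (data frame of `effect_size`, `standard_error`, or `NULL`),
#'   `dataset_ref`, `rendered`.
#' @export
payload_for_llm <- function(dataset, include_data = FALSE, render = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  img <- if (render) render_funnel(dataset) else NULL
  pub <- published_studies(dataset)
  structure(
    list(
      image_base64 = if (render) img$base64 else NA_character_,
      studies = if (include_data) {
        data.frame(effect_size = pub$effect, standard_error = pub$se)
      },
      dataset_ref = dataset_ref(dataset),
      rendered = render
    ),
    class = "llm_payload"
  )
}

#' @export
print.llm_payload <- function(x, ...) {
  cat(sprintf("<llm_payload> ref %s: image %s, study table %s\n",
              x$dataset_ref,
              if (x$rendered) "attached" else "not rendered",
              if (is.null(x$studies)) "absent" else sprintf("with %d rows", nrow(x$studies))))
  invisible(x)
}
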
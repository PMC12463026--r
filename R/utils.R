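#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used to turn a severity fraction into an
#' integer count of suppressed studies: `round_half_up(1.5) == 2`, unlike
#' [base::round()] which rounds half to even.
#'
#' @param x Numeric vector, assumed non-negative here.
#' @return Integer vector.
#' @export
#' @examples
#' round_half_up(c(1.5, 2.5, 4.999))
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Derive a reproducible sub-stream seed
#'
#' Hashes a root seed together with an arbitrary set of labels (simulation
#' cell coordinates, replicate index, ...) into a seed in `[1, 2^31 - 2]`.
#' Every simulation cell and replicate gets its own stream, so individual
#' cells can be regenerated without re-running the whole grid and results do
#' not depend on scheduling order.
#'
#' The hash is a plain polynomial string hash modulo the Mersenne prime
#' 2^31 - 1; it is stable across platforms and R sessions.
#'
#' @param seed Integer root seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' cell_seed(1, "n=15", "tau2=0", rep = 3)
cell_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), function(x) paste(format(x), collapse = ","),
                                      character(1))),
               collapse = "|")
  m <- 2147483647 # 2^31 - 1
  h <- 17
  for (code in utf8ToInt(key)) {
    # h <- (h * 31 + code) %% m, kept in double precision (< 2^53, exact)
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Check a data frame of studies and return it with canonical columns.
# Accepts `effect` + `se` columns; `study_id` added when absent.
as_study_tbl <- function(data, min_n = 2L, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame of studies with `effect` and `se` columns.",
                 call = call)
  }
  missing_cols <- setdiff(c("effect", "se"), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("`data` is missing column(s): ",
                        paste0("`", missing_cols, "`", collapse = ", "), "."),
                 call = call)
  }
  out <- tibble::as_tibble(data)
  if (!"study_id" %in% names(out)) {
    out$study_id <- seq_len(nrow(out))
  }
  if (nrow(out) < min_n) {
    rlang::abort(paste0("At least ", min_n, " studies are required, got ", nrow(out), "."),
                 call = call)
  }
  if (!all(is.finite(out$effect)) || !all(is.finite(out$se))) {
    rlang::abort("`effect` and `se` must be finite.", call = call)
  }
  if (any(out$se <= 0)) {
    rlang::abort("All standard errors must be strictly positive.", call = call)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
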
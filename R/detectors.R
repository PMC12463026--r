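## Contextual prompt text handed to multimodal detectors. The summary block
## explains what a funnel plot shows; the criteria block lists the four
## visual checks; the combined suffix asks the model to corroborate the
## image with the study table. The closing instruction forces the binary
## "Present"/"Absent" output the parser expects.

prompt_summary <- paste(
  "A funnel plot is commonly used to assess publication bias in",
  "meta‐analyses. Each point on the funnel plot represents an individual",
  "study. The vertical axis (y‐axis) shows a measure of precision (e.g.,",
  "standard error), and the horizontal axis (x‐axis) indicates the effect",
  "size. In the absence of publication bias, the funnel plot should",
  "resemble a symmetric inverted triangle. Asymmetry in the funnel plot may",
  "suggest publication bias."
)

prompt_criteria <- paste(
  "Criteria to make the decision based on plots:",
  "1. Symmetry around the overall effect size—look for symmetry (minimal",
  "or no bias) or asymmetry with visible gaps (potential bias).",
  "2. Distribution of studies by precision—check if high‐precision studies",
  "cluster around the mean effect size, and if low‐precision studies are",
  "scattered symmetrically (balanced distribution = no bias, skewed",
  "clustering = potential bias).",
  "3. Effect size trends—identify if smaller studies show larger effects",
  "(no systematic change = minimal/no bias, clear trend = potential bias).",
  "4. Missing study patterns—look for gaps in expected regions, indicating",
  "selective publication (no gap = no bias, noticeable gaps = potential",
  "bias)."
)

prompt_combined_suffix <- paste(
  "Assess the symmetry of the funnel plot by examining the relationship",
  "between effect sizes and standard errors, where each point represents a",
  "trial. Supplement visual input with numerical input by analyzing the",
  "underlying data, including the distribution of effect sizes across",
  "different standard error levels, to provide a comprehensive evaluation",
  "of publication bias."
)

prompt_instruction <- paste(
  "Based on the criteria above, decide whether publication bias is present",
  "in this meta-analysis. The output is Present/Absent of PB. Answer with",
  "exactly one word: Present or Absent."
)

#' Assemble the detector prompt for a payload
#'
#' Builds the contextual prompt for one funnel-plot query: a summary of what
#' a funnel plot shows, the four visual decision criteria, and — in
#' `"combined"` mode only — the suffix directing the model to corroborate
#' the image against the study-level data table. The bundle keeps the
#' payload alongside the text so a detector receives everything in one
#' object.
#'
#' @param mode `"visual"` (image only) or `"combined"` (image plus study
#'   table). The payload must be consistent with the mode: `"combined"`
#'   requires a payload built with `include_data = TRUE`, `"visual"` one
#'   without the study table.
#' @param payload An `llm_payload` from [payload_for_llm()].
#' @return An object of class `prompt_bundle`: list with `mode`,
#'   `context_text`, `criteria_text`, `combined_suffix` (`NULL` in visual
#'   mode), `instruction`, `payload`.
#' @export
build_prompt <- function(mode = c("visual", "combined"), payload) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(payload, "llm_payload"))
  has_data <- !is.null(payload$studies)
  if (mode == "combined" && !has_data) {
    rlang::abort("`mode = \"combined\"` needs a payload built with `include_data = TRUE`.")
  }
  if (mode == "visual" && has_data) {
    rlang::abort("`mode = \"visual\"` must not carry a study table; rebuild the payload with `include_data = FALSE`.")
  }
  structure(
    list(
      mode = mode,
      context_text = prompt_summary,
      criteria_text = prompt_criteria,
      combined_suffix = if (mode == "combined") prompt_combined_suffix,
      instruction = prompt_instruction,
      payload = payload
    ),
    class = "prompt_bundle"
  )
}

#' Full prompt text of a bundle
#'
#' @param bundle A `prompt_bundle`.
#' @return A single string (the study table itself is not inlined here; it
#'   travels in the payload).
#' @export
prompt_text <- function(bundle) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  paste(c(bundle$context_text, bundle$criteria_text, bundle$combined_suffix,
          bundle$instruction), collapse = "\n\n")
}

#' Parse a detector response into a verdict
#'
#' Case-insensitive, word-boundary detection of the tokens "present" and
#' "absent". Negation phrases ("no publication bias", "no evidence of
#' publication bias", "absence of publication bias") count as absent
#' signals; "presence of publication bias" counts as a present signal. A
#' response yielding signals of both classes, or of neither, is
#' unparseable — a value, not an error.
#'
#' @param text A single response string.
#' @return One of `"present"`, `"absent"`, `"unparseable"`.
#' @export
#' @examples
#' parse_response("Publication bias: Present")
#' parse_response("There is no publication bias in this plot.")
parse_response <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    return("unparseable")
  }
  x <- tolower(text)
  absent_phrases <- c("no (evidence of )?publication bias", "absence of publication bias")
  present_phrases <- c("presence of publication bias")
  signals <- c(
    absent = any(vapply(absent_phrases, function(p) grepl(paste0("\\b", p, "\\b"), x),
                        logical(1))),
    present = any(vapply(present_phrases, function(p) grepl(paste0("\\b", p, "\\b"), x),
                         logical(1)))
  )
  # Strip matched phrases before the bare-token scan so their inner words
  # do not double-count.
  for (p in c(absent_phrases, present_phrases)) {
    x <- gsub(paste0("\\b", p, "\\b"), " ", x)
  }
  signals["absent"] <- signals[["absent"]] || grepl("\\babsent\\b", x)
  signals["present"] <- signals[["present"]] || grepl("\\bpresent\\b", x)
  if (xor(signals[["present"]], signals[["absent"]])) {
    if (signals[["present"]]) "present" else "absent"
  } else {
    "unparseable"
  }
}

#' Construct a detector
#'
#' A detector is a named object wrapping a query function
#' `fun(bundle, truth)` that returns one raw response string per call.
#' Deterministic detectors (the statistical tests, the constant mocks) are
#' queried once; stochastic ones (chat models, scripted mocks) are queried
#' `repeats` times under the agreement rule. Only detectors explicitly
#' marked `uses_truth` (the test-only oracle) ever receive the ground-truth
#' label; everything else sees just the prompt bundle.
#'
#' @param id Detector identifier used in logs.
#' @param fun Function of `(bundle, truth)` returning a character scalar.
#' @param deterministic Is one query enough?
#' @param uses_truth Should the pipeline pass the ground-truth label
#'   (test-only detectors)?
#' @return An object of class `pb_detector`.
#' @export
new_detector <- function(id, fun, deterministic = FALSE, uses_truth = FALSE) {
  stopifnot(is.character(id), length(id) == 1, is.function(fun))
  structure(
    list(id = id, fun = fun, deterministic = deterministic, uses_truth = uses_truth),
    class = "pb_detector"
  )
}

#' @export
print.pb_detector <- function(x, ...) {
  cat(sprintf("<pb_detector> %s (%s%s)\n", x$id,
              if (x$deterministic) "deterministic" else "stochastic",
              if (x$uses_truth) ", sees ground truth - test only" else ""))
  invisible(x)
}

#' Built-in mock and statistical detectors
#'
#' `detector_always()` answers with a constant verdict; `detector_oracle()`
#' reads the ground-truth label (test-only upper bound — the pipeline
#' passes it the truth explicitly, it is never reachable from the payload);
#' `detector_scripted()` replays a fixed sequence of raw responses;
#' `detector_egger()` wraps [egger_test()] around the study table carried
#' in a combined-mode payload.
#'
#' @param verdict `"present"` or `"absent"`.
#' @return A `pb_detector`.
#' @export
detector_always <- function(verdict = c("present", "absent")) {
  verdict <- rlang::arg_match(verdict)
  word <- if (verdict == "present") "Present" else "Absent"
  new_detector(
    id = paste0("always-", verdict),
    fun = function(bundle, truth = NULL) word,
    deterministic = TRUE
  )
}

#' @rdname detector_always
#' @export
detector_oracle <- function() {
  new_detector(
    id = "oracle",
    fun = function(bundle, truth = NULL) {
      if (is.null(truth)) rlang::abort("The oracle detector needs the ground-truth label.")
      if (truth) "Present" else "Absent"
    },
    deterministic = TRUE,
    uses_truth = TRUE
  )
}

#' @rdname detector_always
#' @param responses Character vector replayed in order (recycled).
#' @export
detector_scripted <- function(responses) {
  stopifnot(is.character(responses), length(responses) >= 1)
  i <- 0L
  new_detector(
    id = "scripted",
    fun = function(bundle, truth = NULL) {
      i <<- i %% length(responses) + 1L
      responses[i]
    },
    deterministic = FALSE
  )
}

#' @rdname detector_always
#' @param alpha Two-sided level for the wrapped Egger test.
#' @export
detector_egger <- function(alpha = 0.05) {
  new_detector(
    id = "egger",
    fun = function(bundle, truth = NULL) {
      studies <- bundle$payload$studies
      if (is.null(studies)) {
        rlang::abort("The Egger-backed detector needs a combined-mode payload (include_data = TRUE).")
      }
      tbl <- tibble::tibble(effect = studies$effect_size, se = studies$standard_error)
      if (egger_test(tbl, alpha = alpha)$flagged) "Present" else "Absent"
    },
    deterministic = TRUE
  )
}

#' Chat-completions detector over HTTP
#'
#' Queries a chat-completions-style endpoint with the prompt text and the
#' base64-embedded funnel-plot image, one image per request. Transport
#' failures are retried with exponential backoff (3 attempts) before a
#' `detector-unavailable` error is raised. The auth token is read from an
#' environment variable, never stored in the detector. Requires the `curl`
#' package; nothing in the test suite exercises the network.
#'
#' @param endpoint Full chat-completions URL.
#' @param model Model identifier sent in the request body.
#' @param api_key_env Name of the environment variable holding the bearer
#'   token.
#' @param temperature Optional sampling temperature; `NULL` leaves the
#'   service default in place.
#' @param timeout_s Per-request timeout in seconds.
#' @return A `pb_detector` (stochastic: queried five times by default).
#' @export
detector_http <- function(endpoint, model, api_key_env = "PB_DETECTOR_API_KEY",
                          temperature = NULL, timeout_s = 120) {
  rlang::check_installed("curl", reason = "to query an HTTP detector")
  new_detector(
    id = paste0("http-", model),
    fun = function(bundle, truth = NULL) {
      body <- chat_request_body(bundle, model, temperature)
      key <- Sys.getenv(api_key_env, unset = "")
      h <- curl::new_handle(timeout = timeout_s)
      curl::handle_setheaders(h,
        "Content-Type" = "application/json",
        "Authorization" = paste("Bearer", key)
      )
      curl::handle_setopt(h, postfields = jsonlite::toJSON(body, auto_unbox = TRUE))
      last_err <- NULL
      for (attempt in 1:3) {
        res <- tryCatch(curl::curl_fetch_memory(endpoint, handle = h), error = identity)
        if (!inherits(res, "error") && res$status_code < 500) {
          parsed <- jsonlite::fromJSON(rawToChar(res$content), simplifyVector = FALSE)
          return(parsed$choices[[1]]$message$content %||% "")
        }
        last_err <- res
        Sys.sleep(2^attempt * 0.5)
      }
      rlang::abort(
        sprintf("detector-unavailable: %s unreachable after 3 attempts", endpoint),
        parent = if (inherits(last_err, "error")) last_err
      )
    },
    deterministic = FALSE
  )
}

# One-image-at-a-time chat request in the OpenAI-compatible shape.
chat_request_body <- function(bundle, model, temperature = NULL) {
  content <- list(list(type = "text", text = prompt_text(bundle)))
  if (!is.na(bundle$payload$image_base64)) {
    content <- c(content, list(list(
      type = "image_url",
      image_url = list(url = paste0("data:image/png;base64,", bundle$payload$image_base64))
    )))
  }
  if (!is.null(bundle$payload$studies)) {
    content <- c(content, list(list(
      type = "text",
      text = jsonlite::toJSON(list(studies = bundle$payload$studies), digits = NA)
    )))
  }
  body <- list(model = model, messages = list(list(role = "user", content = content)))
  if (!is.null(temperature)) body$temperature <- temperature
  body
}

#' Query a detector under the strict agreement rule
#'
#' Runs the detector `repeats` times (default five, the stability rule for
#' stochastic models; deterministic detectors are run once) and accepts a
#' verdict only when every parsed run is identical: all `"present"` gives
#' `PRESENT`, all `"absent"` gives `ABSENT`, all unparseable gives
#' `UNPARSEABLE`, and any other pattern is `INCONSISTENT`. Raw transcripts
#' are kept verbatim for audit.
#'
#' @param detector A `pb_detector`.
#' @param bundle A `prompt_bundle`.
#' @param repeats Number of queries; defaults to 1 for deterministic
#'   detectors and 5 otherwise.
#' @param truth Ground-truth label, forwarded only to `uses_truth`
#'   detectors.
#' @return An object of class `detector_decision`: list with `verdict`
#'   (`"present"`, `"absent"`, `"inconsistent"` or `"unparseable"`),
#'   `runs` (raw responses), `parsed` (per-run verdicts), `detector_id`.
#' @export
#' @examples
#' bundle <- build_prompt("visual", payload_for_llm(
#'   generate_dataset(scenario_config(15, seed = 1)), render = FALSE))
#' decide_with_agreement(detector_always("present"), bundle)
decide_with_agreement <- function(detector, bundle, repeats = NULL, truth = NULL) {
  stopifnot(inherits(detector, "pb_detector"), inherits(bundle, "prompt_bundle"))
  repeats <- repeats %||% (if (detector$deterministic) 1L else 5L)
  if (repeats < 1) rlang::abort("`repeats` must be at least 1.")
  if (!detector$uses_truth) truth <- NULL
  runs <- character(repeats)
  for (i in seq_len(repeats)) {
    runs[i] <- detector$fun(bundle, truth)
  }
  parsed <- vapply(runs, parse_response, character(1), USE.NAMES = FALSE)
  verdict <- if (length(unique(parsed)) == 1) {
    parsed[1] # unanimous, including unanimously unparseable
  } else {
    "inconsistent"
  }
  structure(
    list(verdict = verdict, runs = runs, parsed = parsed,
         detector_id = detector$id),
    class = "detector_decision"
  )
}

#' @export
print.detector_decision <- function(x, ...) {
  cat(sprintf("<detector_decision> %s: %s (%d run(s): %s)\n",
              x$detector_id, toupper(x$verdict), length(x$runs),
              paste(x$parsed, collapse = ", ")))
  invisible(x)
}

#' Write detector transcripts as JSON lines
#'
#' One line per run, carrying the addressing columns of the decision log
#' plus the verbatim response, for audit.
#'
#' @param decisions A decision-log tibble as produced by [run_grid()] (must
#'   carry a `runs` list-column).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(decisions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cols <- intersect(c("n", "tau2", "severity", "selection", "replicate",
                      "detector", "mode", "verdict"), names(decisions))
  for (i in seq_len(nrow(decisions))) {
    runs <- decisions$runs[[i]]
    for (j in seq_along(runs)) {
      rec <- c(as.list(decisions[i, cols]),
               list(run_index = j, response = runs[j],
                    parsed = parse_response(runs[j]),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
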
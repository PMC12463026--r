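make_bundle <- function(mode = "visual", n = 8, severity = 1 / 5, seed = 5) {
  ds <- make_dataset(n = n, severity = severity, seed = seed)
  build_prompt(mode, payload_for_llm(ds, include_data = (mode == "combined"),
                                     render = FALSE))
}

test_that("prompts carry the mode-specific contextual text", {
  visual <- make_bundle("visual")
  expect_match(visual$context_text, "symmetric inverted triangle")
  expect_match(visual$criteria_text, "Symmetry around the overall effect size")
  expect_match(visual$criteria_text, "Missing study patterns")
  expect_null(visual$combined_suffix)
  expect_false(grepl("comprehensive evaluation of publication bias",
                     prompt_text(visual)))

  combined <- make_bundle("combined")
  expect_match(combined$combined_suffix, "comprehensive evaluation of publication bias")
  expect_match(prompt_text(combined), "symmetric inverted triangle")
  expect_match(prompt_text(combined), "Present/Absent")
})

test_that("mode and payload must be consistent", {
  ds <- make_dataset(n = 8, severity = 1 / 5)
  with_data <- payload_for_llm(ds, include_data = TRUE, render = FALSE)
  without <- payload_for_llm(ds, include_data = FALSE, render = FALSE)
  expect_error(build_prompt("combined", without), "include_data")
  expect_error(build_prompt("visual", with_data), "study table")
})

test_that("responses parse by word-boundary tokens with negation awareness", {
  expect_equal(parse_response("Publication bias: Present"), "present")
  expect_equal(parse_response("absent"), "absent")
  expect_equal(parse_response("ABSENT."), "absent")
  expect_equal(parse_response("There is no publication bias here."), "absent")
  expect_equal(parse_response("no evidence of publication bias"), "absent")
  expect_equal(parse_response("The absence of publication bias is clear"), "absent")
  expect_equal(parse_response("the presence of publication bias is likely"), "present")
  expect_equal(parse_response("the plot is present and absent of bias"), "unparseable")
  expect_equal(parse_response("representative presentation"), "unparseable")
  expect_equal(parse_response(""), "unparseable")
  expect_equal(parse_response(NA_character_), "unparseable")
})

test_that("only unanimous five-run patterns yield a verdict", {
  bundle <- make_bundle()
  words <- c("Present", "Absent")
  patterns <- expand.grid(rep(list(1:2), 5))
  for (i in seq_len(nrow(patterns))) {
    responses <- words[unlist(patterns[i, ])]
    decision <- decide_with_agreement(detector_scripted(responses), bundle,
                                      repeats = 5)
    expected <- if (all(responses == "Present")) {
      "present"
    } else if (all(responses == "Absent")) {
      "absent"
    } else {
      "inconsistent"
    }
    expect_equal(decision$verdict, expected,
                 label = paste(responses, collapse = ","))
    expect_length(decision$runs, 5)
  }
})

test_that("unparseable runs follow the agreement rule", {
  bundle <- make_bundle()
  all_bad <- decide_with_agreement(detector_scripted(rep("???", 5)), bundle,
                                   repeats = 5)
  expect_equal(all_bad$verdict, "unparseable")

  mixed <- decide_with_agreement(
    detector_scripted(c("Present", "???", "Present", "Present", "Present")),
    bundle, repeats = 5
  )
  expect_equal(mixed$verdict, "inconsistent")
})

test_that("deterministic detectors are queried once and are stable", {
  bundle <- make_bundle()
  d1 <- decide_with_agreement(detector_always("present"), bundle)
  expect_length(d1$runs, 1)
  expect_equal(d1$verdict, "present")
  d2 <- decide_with_agreement(detector_always("present"), bundle)
  expect_identical(d1$verdict, d2$verdict)

  abs5 <- decide_with_agreement(detector_always("absent"), bundle, repeats = 5)
  expect_equal(abs5$verdict, "absent")
})

test_that("the oracle detector sees the truth only via the explicit channel", {
  bundle <- make_bundle()
  oracle <- detector_oracle()
  expect_error(decide_with_agreement(oracle, bundle), "ground-truth")
  expect_equal(decide_with_agreement(oracle, bundle, truth = TRUE)$verdict,
               "present")
  expect_equal(decide_with_agreement(oracle, bundle, truth = FALSE)$verdict,
               "absent")
  # non-oracle detectors never receive the truth
  probe <- new_detector("probe", function(bundle, truth = NULL) {
    if (is.null(truth)) "Absent" else "Present"
  }, deterministic = TRUE)
  expect_equal(decide_with_agreement(probe, bundle, truth = TRUE)$verdict,
               "absent")
})

test_that("the Egger-backed detector reproduces the direct test", {
  ds <- make_dataset(n = 20, severity = 1 / 3, seed = 9)
  bundle <- build_prompt("combined", payload_for_llm(ds, include_data = TRUE,
                                                     render = FALSE))
  decision <- decide_with_agreement(detector_egger(), bundle)
  direct <- egger_test(published_studies(ds))
  expect_equal(decision$verdict == "present", direct$flagged)

  visual <- build_prompt("visual", payload_for_llm(ds, render = FALSE))
  expect_error(decide_with_agreement(detector_egger(), visual), "combined")
})

test_that("chat request bodies embed one image and no ground truth", {
  ds <- make_dataset(n = 6, severity = 1 / 5, seed = 13)
  img_bundle <- build_prompt("visual", payload_for_llm(ds, include_data = FALSE))
  body <- biasbench:::chat_request_body(img_bundle, model = "test-model")
  types <- vapply(body$messages[[1]]$content, `[[`, character(1), "type")
  expect_equal(sum(types == "image_url"), 1)
  expect_equal(body$model, "test-model")
  expect_null(body$temperature)
  with_temp <- biasbench:::chat_request_body(img_bundle, "m", temperature = 0.2)
  expect_equal(with_temp$temperature, 0.2)
})
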
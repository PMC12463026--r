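Package: biasbench
Title: Simulation Benchmark for Publication-Bias Detectors in Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates random-effects meta-analyses with controlled selective
    non-publication, fits the normal-normal model by restricted maximum
    likelihood (Fisher scoring), renders funnel plots as reproducible PNG
    payloads, and benchmarks publication-bias detectors: from-scratch
    implementations of Egger's regression test, Begg's rank correlation test
    and the trim-and-fill method, plus a pluggable interface for multimodal
    chat-model detectors queried under a strict five-run agreement rule.
    Detector decisions are scored with confusion-matrix metrics (sensitivity,
    specificity, PPV, NPV, F1, consistency rate) with replication-based
    percentile confidence intervals, and a power/type-I benchmark over the
    full simulation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ragg,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    curl,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
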
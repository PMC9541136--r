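Package: occbias
Title: Sampling-Bias Screening and Risk-of-Bias Assessment for Species
    Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structured screening of species occurrence records ("biological
    records") for sampling biases that can undermine inference about temporal
    trends in biodiversity. Users declare a statistical target population
    (geographic, temporal, taxonomic and optionally environmental extents and
    resolutions); the package computes per-period bias-screening heuristics on
    the records (a nearest-neighbour index against simulated complete spatial
    randomness references with bootstrap uncertainty, periods-sampled maps,
    per-cell density trajectories, taxonomic and environmental coverage
    series) and assembles a versioned, machine-readable 17-question
    risk-of-bias assessment document with quantitative evidence attached.
    A point-process simulator injects known bias mechanisms (clustering,
    drifting spatial windows, uneven taxon preference) to validate that the
    heuristics detect them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    mgcv,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
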
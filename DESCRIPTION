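Package: readbias
Title: Reference-Free Positional Bias Assessment for Short Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control statistics for short-read sequencing data that do
    not require a reference genome. Provides per-position base-call and quality
    profiling, positional k-mer counting with binomial over/under-representation
    tests against reference- or read-pool background models (log-space tail
    probabilities via a Stirling-series approximation), pairwise Kullback-Leibler
    divergence of per-position k-mer distributions, a uniform-sampling read
    simulator with empirical per-position error profiles for bootstrap
    calibration of expected divergences and effect sizes, artefact filters for
    poly-A fragments and primer prefixes, and synthetic genome/read generators
    with parameterised injected biases for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
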
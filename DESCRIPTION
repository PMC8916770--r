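Package: sigscore
Title: Dropout-Aware Gene Signature Scoring for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-cell gene signature (gene set) scoring for single-cell
    RNA-seq with the rank-and-enrichment JASMINE score, together with
    re-implementations of SCSE, AUCell-style recovery-curve scoring, and
    the ssGSEA running sum, and a benchmarking harness around them:
    Cohen's d contrasts between cell groups, noisy gold-standard gene-set
    simulation, binomial down-sampling null experiments, a floating-gene
    dropout probe, and a synthetic tumor/normal cohort generator with
    known differential-expression truth. Results are tibbles that chain
    with the pipe, with broom-style tidy()/glance() and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
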
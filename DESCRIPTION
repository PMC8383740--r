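Package: tracekin
Title: Dye-Dilution Proliferation Analysis and Receptor Expression Surveys
Version: 0.1.0
Authors@R: person("Tracekin", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of dye-dilution (CellTrace/CFSE) T cell
    proliferation experiments: simulation of labelled division cohorts,
    minimal FCS 3.0/3.1 input/output with gating and downsampling,
    constrained Gaussian-mixture deconvolution of fluorescence histograms
    into per-generation frequencies, precursor-normalized proliferation
    statistics (percent undivided and percent division per generation,
    division/proliferation/expansion indices) with Holm-Sidak adjusted
    condition comparisons, plus a transcriptomic receptor-survey toolkit
    (paralog read grouping, median-of-ratios size factors, TPM/CPM
    normalization, expression-threshold calls, differential-expression
    classification) and ranked-list gene-set enrichment with permutation
    FDR and hypergeometric overlap tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
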
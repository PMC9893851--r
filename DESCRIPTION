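Package: episcreen
Title: Multilevel MHC-I Epitope Identification by Pool-Matrix Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of MHC class I T-cell epitopes from a viral
    proteome by a multilevel screening pipeline: exhaustive 8-11mer
    candidate enumeration, percentile-rank binder classification and
    cross-predictor consensus ranking with stability and host-proteome
    dissimilarity criteria, gene-order quota selection, combinatorial
    horizontal/vertical peptide-pool matrix design, IFN-gamma ELISpot
    screening statistics (two-way ANOVA with Sidak-adjusted per-stimulus
    contrasts), matrix deconvolution to individual epitope hits,
    intracellular cytokine staining (ICS) validation, and epitope
    characterization (novelty annotation, sequence-logo frequency
    matrices, length distributions, proteome coverage). A synthetic-data
    module simulates predictor rank tables with planted binders,
    negative-binomial spot counts with planted responders, and linked ICS
    frequencies, so the whole pipeline is testable end to end without
    external predictors or wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
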
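Package: riboshift
Title: Quantifying Programmed +1 Ribosomal Frameshifting from Ribosome
    Profiling and Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-phased analysis of ribosome-footprint data over
    dual-ORF transcripts that use programmed +1 ribosomal frameshifting,
    in the style of the yeast Ty1/ABP140/EST3/YFS1 shift sites. Provides
    A-site offsetting of footprint 5' ends, sub-codon frame phasing by
    transcript region, a frameshift-efficiency estimator with bootstrap
    confidence intervals, dual-luciferase reporter arithmetic, detection
    of heptameric +1 shift sites and overlapping-ORF architecture in
    homolog mRNAs, reference-projected protein-alignment conservation
    statistics with a neighbor-joining tree builder, and synthetic
    generators for footprint tracks and homolog families with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
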
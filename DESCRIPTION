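Package: dwarfmapr
Title: Bulked-Segregant Mapping of a Semi-Dominant Dwarf Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end identification of the causal mutation behind a
    semi-dominant dwarf phenotype in a biparental cross: Mendelian
    segregation testing by chi-squared goodness of fit, delta(SNP-index)
    bulked-segregant mapping with Monte-Carlo 95% confidence bands,
    variant-effect annotation against gene models (including Aux/IAA
    degron-motif disruption), genetic-property exclusion filtering of
    candidate variants, and allele-specific PCR marker design. Ships a
    synthetic F2 cross and pooled-sequencing simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    dplyr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
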
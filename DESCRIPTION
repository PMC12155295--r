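Package: phylostage
Title: Phylotranscriptomic Indices and Hourglass Tests Across Tumor Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Transcriptome Age Index (TAI) and Transcriptome
    Divergence Index (TDI) from staged bulk expression matrices and gene-level
    evolutionary annotation (phylostrata and dN/dS divergence deciles), and
    tests stage profiles for flat, hourglass and reverse-hourglass patterns
    with gene-label permutation nulls. Also performs phylostratum composition
    analysis of differentially expressed gene lists: per-stratum Fisher exact
    tests with Benjamini-Hochberg correction, a global chi-square against the
    background gene universe, and a bootstrap resampling null. Ships a
    negative-binomial synthetic-data generator with plantable hourglass
    patterns and phylostratum enrichment so the whole pipeline is testable
    without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
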
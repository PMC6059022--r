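Package: dimertarget
Title: Integrin Heterodimer Drug-Target Selection from Tumor Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for nominating integrin heterodimeric receptors as
    anti-cancer drug targets from bulk tumor/normal expression data. Implements
    negative-binomial Wald differential expression on raw counts with
    median-of-ratios size factors and an optional gene-by-sample normalization
    factor matrix, Benjamini-Hochberg false discovery rate control, a
    fold-change/FDR ranking metric for overexpressed subunit genes, absolute
    expression (FPKM) filtering, quantification of ordinal immunohistochemistry
    staining, and rules-based pairing of alpha/beta subunits into the 24
    functional integrin receptors with RNA/IHC evidence integration. Ships a
    negative-binomial synthetic cohort generator so the full pipeline is
    testable without external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    DESeq2,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
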
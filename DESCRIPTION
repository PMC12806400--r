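Package: syncomscreen
Title: Screening Synthetic Microbial Communities from Fermentation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening candidate members of a synthetic microbial
    community (SynCom) from fermentation time-series data. Computes
    taxon-compound association groups (Flavor, Amino-acid) with
    Benjamini-Hochberg control, taxon-taxon co-occurrence networks and
    strong-node (hub) detection, abundance-based Major-group filtering,
    cross-referencing of functional groups into SynCom candidates, and a
    culturability substitution step. Community-assembly analysis includes a
    frequency-weighted Raup-Crick null model, non-metric multidimensional
    scaling, Mantel tests, ANOSIM, and alpha/beta diversity. A synthetic
    fermentation-community generator with a ground-truth ledger supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
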
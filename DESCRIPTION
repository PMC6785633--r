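Package: ladcycle
Title: Periodicity of Lamina-Associated Domain Dynamics Across the
    Circadian Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies lamina-associated domain (LAD) dynamics over a
    circadian time course and detects periodic oscillations in LAD border
    coverage and in gene expression. LAD calls per circadian time point and
    replicate are reduced to per-LAD maximal footprints (cov_max); 5' and 3'
    border positions are standardized to [0,1] time series and tested for
    rhythmicity with a nonparametric JTK_CYCLE rank test (exact null),
    a Lomb-Scargle periodogram, and Fisher chi-square combination of
    p-values. Detected periodicity is validated by circadian-time-order
    randomization, and periodic genes are related to LAD geometry via
    strand-aware gene-to-nearest-LAD distances. A synthetic-data module
    generates toy genomes, LAD time courses and FPKM matrices with known
    injected rhythms so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    tibble,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
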
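Package: oakscape
Title: Landscape Genomics of Two-Lineage Tree Species at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for whole-genome landscape genomics of a
    species split into two deeply diverged lineages, as found in East Asian
    evergreen oaks spanning the East China Sea. Provides invariant-site-aware
    windowed nucleotide diversity, absolute divergence and Hudson FST,
    Tajima's D, PLINK-style detection of runs of homozygosity with the FROH
    inbreeding coefficient, linkage-disequilibrium decay curves with the
    half-maximum decay distance, frequency-based ABBA-BABA D statistics with
    block-jackknife significance, Mantel tests of isolation by distance and
    by environment, redundancy-analysis variance partitioning, latent-factor
    genotype-environment association scans, FST-outlier detection, and the
    risk-of-non-adaptedness (RONA) measure of genomic vulnerability under
    projected climates. A hierarchical Balding-Nichols simulator generates
    genotype, metadata and environment fixtures with known ground truth for
    estimator-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    vegan,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
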
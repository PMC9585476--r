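Package: pbscan
Title: Population Branch Statistic Selection Scans with Gene-Set and
    Uniparental Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scans for branch-specific positive selection using
    the population branch statistic (PBS) built on per-site Weir-Cockerham
    F_ST, with the site filters, percentile thresholds, gene annotation and
    trio-swap contrasts used in whole-genome studies of isolated human
    populations.  Includes a polygenic-selection test that compares per-gene-set
    PBS distributions against the genomic background with one-sided
    Mann-Whitney U tests and Bonferroni control, haplogroup-diversity and
    frequency-PCA summaries of uniparental markers, runs-of-homozygosity
    classification, and a Balding-Nichols trio simulator so every stage can be
    exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
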
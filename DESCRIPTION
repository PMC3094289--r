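Package: arborquant
Title: Quantitative Morphometry of Stereotyped Mechanosensory Axonal Arbors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A synthetic-data-driven pipeline for quantitative analysis of
    stereotyped axonal arbors of identified mechanosensory neurons. Generates
    ground-truth arbors and cohorts calibrated to per-genotype morphometric
    targets, renders single- and two-channel fluorescence image stacks, traces
    arbors and axonal varicosities back out of the images, applies branch-length
    filtering and ganglion-width normalization, extracts consensus skeletons by
    frequency thresholding with branch-correspondence matching, quantifies
    immunohistochemistry intensity ratios, and reports cohort statistics
    (Mann-Whitney, Kolmogorov-Smirnov, chi-squared, ANOVA with Bonferroni
    correction) in a summary-table format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Software, CellBiology, Neuroscience
Config/testthat/edition: 3
RoxygenNote: 7.3.3
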
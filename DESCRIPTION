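Package: balenrich
Title: Detection Limits and Lung-Enrichment Outlier Tests for Replicate
    16S rRNA Gene OTU Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for identifying bacterial lineages
    genuinely enriched in bronchoalveolar lavage (BAL) samples against a
    background of upper-respiratory-tract carry-over, from replicate 16S
    rRNA gene OTU count tables. Models replicate counts with
    beta-binomial and Dirichlet-multinomial distributions, estimates
    over-dispersion by the method of moments and by maximum likelihood,
    computes sequencing-depth detection limits (critical proportions for
    95% detection), and provides single-sided outlier tests for lung
    enrichment -- pairwise sample comparisons with an analytic
    beta-binomial null, and pooled-replicate comparisons with a
    Monte-Carlo null -- with false discovery rate control. Includes a
    synthetic-data generator emulating paired BAL/oral-wash study
    designs with planted enrichment, readers and writers for classic
    tab-delimited OTU tables and sample sheets, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    biomformat
Config/testthat/edition: 3
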
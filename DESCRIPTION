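Package: methsmooth
Title: Smoothed Methylation Profiles and Differentially Methylated
    Regions from Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    (WGBS) data: M-bias quality control on read-level methylation
    measurements, local-likelihood smoothing of per-CpG binomial counts
    (tricube-weighted logit-quadratic fits in adaptive 70-CpG / 2 kb
    windows), detection of differentially methylated regions (DMRs) and
    large hypomethylated blocks with a signal-to-noise t-statistic that
    accounts for biological variability (75th-percentile variance
    flooring, running-mean variance smoothing, slow-component correction
    for cancer analyses), a Fisher's-exact-test baseline DMR finder, and
    region-level evaluation machinery (gold-standard construction,
    overlap/direction ROC curves, TSS-proximity enrichment). Includes a
    synthetic WGBS data generator with planted DMRs, blocks and
    read-position bias for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
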
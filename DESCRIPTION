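Package: splicescreen
Title: Pan-Cancer Exon-Skipping Screens with Planted-Truth Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for screening tumor-versus-normal
    alternative-splicing changes across cancer cohorts. Reads SpliceSeq-style
    percent-spliced-in (PSI) tables, FPKM expression tables, MAF-style somatic
    mutation tables and clinical records; ranks frequently mutated genes
    against a driver catalogue; summarizes and ranks exon-skipping events by
    mean absolute delta-PSI across cancer types; calls per-patient paired
    tumor/normal splicing alterations at a delta-PSI threshold; screens
    splicing factors by correlating factor expression with event PSI; and
    stratifies patients by mutation status, expression splits and marker
    flags for Kaplan-Meier and log-rank survival comparison. A synthetic
    multi-cohort generator with planted effects (a differentially spliced
    event, an anti-correlated regulator, rule-coupled marker expression and
    stratum-dependent survival hazards) provides ground truth for end-to-end
    validation.
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
    utils
Suggests:
    multcomp,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
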
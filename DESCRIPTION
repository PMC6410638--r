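Package: panelcohort
Title: Cohort Analysis of Matched Tumor-Normal Targeted Sequencing Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Cohort-level analysis of somatic and germline variant calls from
    matched tumor-normal targeted gene panels, built for comparing a carcinoma
    group against its precursor-lesion group. Provides somatic variant quality
    filters; tumor mutational burden (TMB) with hypermutation and
    DNA-damage-repair flags and a rank-based group comparison; a region-based
    log2 depth-ratio (LRR) copy-number caller with a majority rule per gene;
    per-gene mutation-frequency contingency testing (Yates-corrected
    chi-square or two-sided Fisher exact) with co-mutation analysis; rule-based
    germline pathogenic-variant screening with Lynch-syndrome classification
    and recessive-gene zygosity handling; and a seeded synthetic-cohort
    generator for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
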
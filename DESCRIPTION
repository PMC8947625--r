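Package: crctriage
Title: Somatic Variant Triage and Mutation-Landscape Analysis for
    Targeted Colorectal Cancer Panels
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tumor-only somatic variant triage for targeted multigene
    colorectal cancer (CRC) panels, and cohort mutation-landscape
    summaries built on the retained calls. Implements a multi-layer
    filtering cascade (read depth and call quality gates, functional
    class gates, COSMIC/ClinVar/HGMD database triage, population
    minor-allele-frequency cutoffs, pooled-normal subtraction from a
    non-neoplastic control group, and a damaging-prediction consensus
    over SIFT, PolyPhen-2 and CADD), with a per-variant audit trace.
    Downstream tools compute group-occupancy partitions of variants
    (CRC-specific versus shared with precursor lesions), diagnostic
    yield, mutational burden, per-gene summaries, exon and protein
    hotspots, novelty flags, anti-EGFR resistance-marker rules,
    oncoplot and lollipop matrices, and hypergeometric gene-set
    over-representation analysis. A seeded synthetic-cohort generator
    with ground-truth labels makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
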
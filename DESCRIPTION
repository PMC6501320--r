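Package: dcisburden
Title: Gene-Based Rare-Variant Burden Testing for Early-Onset DCIS Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-variant-calling analysis for targeted germline sequencing
    panels of breast cancer predisposition genes (BRCA2, BRCA1, CHEK2, PALB2,
    TP53) in ductal carcinoma in situ (DCIS) case-control cohorts. Provides
    quality-control filtering of annotated variant calls, rule-based
    pathogenicity classification with ClinVar-label precedence, carrier-based
    per-gene burden testing (one-sided Fisher's exact test, odds ratios with
    Woolf/logit confidence intervals, external-control replication), case-only
    and stratified carrier-frequency analyses, Monte-Carlo power estimation,
    and a synthetic-cohort generator with known ground truth so the whole
    pipeline can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
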
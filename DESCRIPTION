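Package: htxcnv
Title: Rare Copy-Number Variant Discovery and Candidate-Gene
    Prioritization for Heterotaxy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for chromosomal-microarray copy-number
    variant (CNV) call sets from heterotaxy patients. Implements
    interval-based rarity filtering against a common-CNV population
    database (size, marker support, population frequency and overlap
    fraction, control-cohort screening), genic-impact classification of
    dosage events against gene models (genic deletion, full-gene
    duplication, internal duplication), curated gene-set candidate
    prioritization with a known-laterality-gene screen, five-criterion
    rare-variant exome filtering, and the 2x2 contingency statistics
    (Yates-corrected chi-squared, Fisher's exact test) used to score
    zebrafish laterality phenotypes. Ships seeded synthetic-data
    generators with ground-truth labels so every stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
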
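Package: rarecarrier
Title: Control-Free Rare-Variant Overrepresentation Testing in Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Burden testing of rare germline variants in a disease-centralized
    cohort without matched controls. Implements genotype- and variant-level
    quality control (genotype quality, depth, allele balance, Hardy-Weinberg
    exact test, call rate), rare-variant selection from ANNOVAR-style
    functional annotation, a per-variant binomial carrier-probability test
    against population (gnomAD-style) allele frequencies under dominant and
    recessive inheritance with Bonferroni adjustment, and a gene-level CAST
    collapse with damaging-predictor voting and protein-length normalized
    mutation fractions. Includes a fully synthetic cohort generator so the
    whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
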
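Package: bestgene
Title: Bidirectional Effect Gene Screening and Rare-Variant Drug-Target Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate drug targets with bidirectional allelic
    series (genes carrying both gain- and loss-of-function variants with
    opposing effects on the same phenotype axis), quantifies how such genetic
    evidence enriches for clinical-trial approval via phase-transition
    relative risks, and validates height/idiopathic-short-stature targets
    with a rare-variant exome association battery (burden and SKAT tests over
    consequence masks), polygenic-score stratification with heterogeneity
    statistics, and integration of cellular functional readouts. Includes a
    fully seeded synthetic-data generator emulating the statistical structure
    of mutation catalogs, clinical-trial outcome tables, exome cohorts and
    functional assays, so the whole pipeline is testable without licensed or
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
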
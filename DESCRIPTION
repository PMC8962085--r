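Package: varitriage
Title: Automated Exome Variant Triage and Daily Knowledge-Base Reanalysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for automated clinical exome interpretation and
    prospective reanalysis. Combines ACMG/AMP evidence codes at modulated
    strengths into five-tier variant classifications, scores patient-disease
    phenotype fit with an information-content based similarity over the Human
    Phenotype Ontology, applies report-triage rules (positive, inconclusive,
    negative) including compound-heterozygote logic and secondary-finding
    flags, and replays a daily reanalysis loop driven by dated knowledge-base
    snapshot diffs with review-suppression bookkeeping and cohort metrics.
    Ships a synthetic cohort and knowledge-base timeline generator so the
    whole pipeline is testable without external database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
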
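Package: pregreg
Title: Pregnancy Register Construction from Linked Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a research-ready pregnancy register from linked primary
    care (GP) and Hospital Episode Statistics (HES Maternity, Admitted
    Patient Care, and Procedures) event tables. Coded events are mapped to
    delivery and pregnancy-loss outcome categories, deduplicated, and
    same-day conflicts resolved by clinical priority hierarchies; pregnancy
    episodes are identified in three phases with minimum-gap and
    gestation-consistency rules; each episode receives an estimated date of
    conception through a five-level dating hierarchy with outcome-specific
    imputation. Includes a seeded synthetic linked-EHR generator for ground
    truth testing, internal validation (cross-source positive predictive
    value, source-overlap counts, postnatal linkage), directly
    age-standardised rates, and demographic reporting with small-count
    suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
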
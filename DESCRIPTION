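Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: An end-to-end pharmacovigilance analysis pipeline for FAERS-style
    quarterly adverse-event report tables: reads the dollar-delimited ASCII
    dialect with row-level quarantine, deduplicates case versions by the FDA
    rule (latest FDA_DT, then highest PRIMARYID), assembles a primary-suspect
    drug cohort by normalized name matching, and computes four
    disproportionality statistics (ROR, PRR with Pearson chi-squared, the
    BCPNN information component, and the empirical Bayes geometric mean) at
    MedDRA preferred-term and system-organ-class level, with the conventional
    per-algorithm signal criteria and a four-way consensus flag. Demographic,
    annual-distribution and time-to-onset summaries mirror the standard
    descriptive tables. A synthetic FAERS-like data generator with known
    ground-truth reporting-rate ratios makes every stage testable without the
    FAERS download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
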
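Package: longdeid
Title: Risk-Based De-Identification of Longitudinal Health Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing longitudinal health insurance claims data for
    public release under a quantified re-identification risk budget. Implements
    preprocessing transforms (keyed pseudonymization, top-coding, rarity-scored
    claim truncation, high-risk patient removal, provider suppression),
    per-quasi-identifier generalization hierarchies and the lattice of
    generalization states, prosecutor and marketer re-identification risk
    metrics with population class-size estimation from a sampling fraction, a
    per-patient adversary background-knowledge power model for transactional
    data, a longitudinal optimal-lattice-anonymization search driven by
    hierarchical-bootstrap node evaluation with a non-uniform entropy
    information-loss objective, and an independent Monte-Carlo simulated
    re-identification attack with sensitivity variants. A synthetic claims
    generator with controllable equivalence-class structure makes every
    component testable without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
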
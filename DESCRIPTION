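Package: bfcea
Title: Cost-Effectiveness Modelling of Breastfeeding Education and Support Interventions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing a
    breastfeeding education and support intervention added to standard care
    against standard care alone, from an NHS/personal-social-services
    perspective. Combines one-year decision trees for infant gastrointestinal
    infection, respiratory tract infection, acute otitis media and infant
    mortality, a two-state lifetime Markov model for infants saved from death,
    and a three-state breast-cancer Markov model with ten tunnel states and
    half-cycle correction for the mothers. Provides exposure-stratified
    incidence partitioning, QALY discounting, ICER and dominance
    classification, probabilistic sensitivity analysis, two-way deterministic
    grids, scenario analyses, and a synthetic-data generator for the
    age-indexed national-statistics tables the model consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
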
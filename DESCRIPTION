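Package: perivig
Title: Pharmacovigilance Analysis of Immune Checkpoint Inhibitor
    Pericardial Toxicities from Spontaneous-Report Databases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disproportionality analysis of immune checkpoint
    inhibitor (ICI) associated pericardial adverse events in FAERS-style
    spontaneous reporting data. Reads and writes FAERS quarterly ASCII
    extracts, deduplicates case versions, applies a MedDRA preferred-term
    case definition and an ICI drug dictionary to build case cohorts,
    computes reporting odds ratios and Bayesian information components
    with their signal criteria for configurable drug/comparator designs,
    and reproduces descriptive clinical analyses (characteristics tables,
    stratified fatality rates, time-to-onset summaries and group tests).
    Includes a fully parameterised synthetic FAERS generator with a
    ground-truth ledger for method evaluation, and a deterministic
    fixture cohort whose two-way fatality margins match a published
    characteristics table exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Pharmacogenomics, Epidemiology, Software
RoxygenNote: 7.3.3
Collate:
    'perivig-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'dictionaries.R'
    'faers-io.R'
    'cohort.R'
    'dispro.R'
    'clinical.R'
    'synth.R'
    'table2-fixture.R'
    'pipeline.R'
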
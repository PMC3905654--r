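Package: bpdcua
Title: Cost-Utility Model of Atypical Antipsychotics in Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing atypical
    antipsychotics (asenapine versus olanzapine) in bipolar disorder. A
    one-year decision tree covering extrapyramidal symptoms, treatment
    switching and significant (>=7%) weight gain feeds a time-dependent
    Markov cohort model of long-term metabolic complications (diabetes,
    hypertension, coronary heart disease, stroke) with an absorbing death
    state. Accrues discounted costs and quality-adjusted life years under
    Ministry-of-Health and societal perspectives, classifies incremental
    cost-utility ratios and dominance, and provides one-way deterministic
    and Monte Carlo probabilistic sensitivity analyses together with an
    individual-level microsimulation used to cross-validate the cohort
    engine. Synthetic generators for life tables and baseline epidemiology
    make the full pipeline runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
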
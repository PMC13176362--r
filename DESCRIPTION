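Package: strokeprev
Title: Microsimulation Cost-Effectiveness Analysis of Primary Stroke
    Prevention in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level discrete-time microsimulation of primary
    stroke prevention in U.S. adults aged 45 years and older with type 2
    diabetes. Generates survey-weighted synthetic cohorts emulating a
    national examination-survey subsample, applies guideline-based
    treatment-escalation policies with stochastic adherence, simulates
    annual competing-risk transitions (stroke, myocardial infarction,
    death) driven by risk-factor hazard ratios, and evaluates enhanced
    prevention scenarios against the status quo with discounted costs and
    quality-adjusted life-years, incremental cost-effectiveness ratios
    with dominance classification, net health benefit, replicate
    uncertainty intervals, and one-way sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
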
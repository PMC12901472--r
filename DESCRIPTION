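Package: adcea
Title: Markov Cohort Cost-Effectiveness Modelling of Anti-Amyloid Therapy in Early Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-state Markov cohort model (mild cognitive impairment, mild,
    moderate and severe dementia due to Alzheimer's disease, and death) for
    lifetime cost-effectiveness analysis of the anti-amyloid antibodies
    lecanemab and aducanumab against standard of care, from a US healthcare
    system perspective. Provides hazard-ratio-based treatment effects on
    annual transition probabilities, age- and stage-dependent mortality,
    discounted accumulation of life-years, quality-adjusted life-years and
    costs, incremental cost-effectiveness ratios with dominance
    classification, value-based price solving, one-way (tornado) sensitivity
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Includes a generator of structurally valid
    synthetic model instances and analytic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
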
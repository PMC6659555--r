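Package: svysmoke
Title: Simulation, Weighting and Bootstrap Variance for Stratified
    Multistage Smoker Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design-based tools for quota-driven stratified multistage
    household surveys of adult smokers. Simulates the full recruitment
    protocol (proportional cluster allocation with a per-stratum floor,
    systematic dwelling selection along a randomised route, household
    screening, next-birthday within-household respondent selection, and
    per-cluster interview quotas) on synthetic national populations;
    computes fieldwork disposition accounting and the derived contact,
    cooperation, eligibility and response rates; constructs four-step
    survey weights (within-household inverse selection probability,
    within-stratum inclusion scaling, post-stratification or raking
    calibration to benchmark smoker margins, and rescaling to mean one);
    and estimates variances and confidence intervals with Rao-Wu rescaled
    bootstrap replicate weights. Ships the fieldwork disposition counts of
    a six-country European smoker survey as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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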
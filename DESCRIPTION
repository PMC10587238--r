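Package: allometherm
Title: Allometric Scaling and Thermal Performance of Fish Metabolism and
    Cardiac Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing body-size and acute-temperature effects on
    fish aerobic metabolism and cardiac thermal tolerance. Converts raw
    intermittent-flow respirometry traces into quality-filtered,
    background-corrected oxygen-uptake (MO2) series and per-fish metabolic
    summaries (maximum and resting metabolic rate, absolute and factorial
    aerobic scope); estimates cardiac thermal-tolerance metrics (Arrhenius
    breakpoint temperature, peak maximum heart rate and its temperature,
    arrhythmia temperature) from per-degree maximum heart-rate series via
    broken-stick regression with a parametric bootstrap; fits ln-ln
    mass-scaling models (mixed models with individual random intercepts for
    repeated measures, simple regressions for one-off traits) with BIC model
    selection, Type II tests and mass-normalization to a reference body
    mass; and computes Q10 thermal sensitivities and Fick-equation slope
    decompositions. Includes a seeded synthetic-data generator emulating the
    statistical structure of an intermittent-flow respirometry and cardiac
    thermal-tolerance study so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    emmeans,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
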
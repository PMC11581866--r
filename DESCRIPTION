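Package: arcsim
Title: Closed-Loop Hemorrhage and Fluid-Resuscitation Simulation with Adaptive Controllers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for physiological closed-loop fluid
    resuscitation. Couples a synthetic swine hemodynamic model (linear
    pressure-volume response to whole blood, pressure-dependent crystalloid
    retention with interstitial redistribution, central venous pressure
    loading, anesthetic-stratified lactate kinetics, and hematocrit dilution)
    with an adaptive resuscitation controller that estimates pressure-volume
    responsiveness by sliding-window regression and infuses at a rate that
    achieves a configured pressure-rise pace, and with a decision-table
    hemorrhage controller that withdraws and reinfuses blood to hold a
    hypotensive target while mixing anticoagulant at a fixed volumetric ratio.
    Runs the full two-event hemorrhage/resuscitation protocol, scores each
    resuscitation event with twelve controller-performance metrics (median
    performance error, median absolute performance error, wobble,
    effectiveness, resuscitation effectiveness, target overshoot, areas
    above/below target, rise time, and infusion-rate statistics), and reads
    and writes plain CSV traces, decision logs, and YAML run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
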
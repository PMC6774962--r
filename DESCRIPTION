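Package: habtrend
Title: Temporal Trends in the Effectiveness of Anti-Predator Interventions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how the effectiveness of non-invasive anti-predator
    interventions changes over time. Computes relative-risk based percent
    damage reduction from treatment/control monitoring counts, builds
    incremental (cumulative) effectiveness trend lines for each monitored
    case, fits continuous piecewise-linear (segmented) regressions with
    breakpoint standard errors and selects the number of breakpoints by AIC,
    classifies trends into least-, slow- and fast-habituation scenarios with
    a counter-productivity flag, and simulates synthetic monitoring cases
    with known ground truth for validation. Includes an exhaustive
    grid-search fitter as an independent reference for the iterative
    segmented estimator, and a pipeline that chains all stages with CSV
    reports and diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
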
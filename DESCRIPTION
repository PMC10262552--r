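Package: polytdm
Title: Simulation and Statistics for TDM-Guided Polymyxin B Dosing Trials
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse therapeutic drug monitoring (TDM)
    strategies for intravenous polymyxin B in critically ill patients with
    carbapenem-resistant Gram-negative infections.  Provides an analytic
    two-compartment infusion pharmacokinetic model, a limited-sampling
    estimator of the steady-state 24-h area under the concentration-time
    curve (ssAUC0-24) from a trough/2-h concentration pair, the 50-100
    mg.h/L therapeutic-window dose-titration protocol with +/-25 mg steps,
    composite 14-day clinical response and KDIGO acute kidney injury
    classifiers, a virtual-patient cohort generator, and the randomized
    trial statistics (relative risk and risk difference with log-Wald,
    Wald and Newcombe hybrid-score intervals, Pearson chi-square, exact
    tests, Kaplan-Meier/log-rank/Cox machinery, and two-proportion sample
    size and power, both closed-form and Monte Carlo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
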
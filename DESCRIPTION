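Package: ssbtax
Title: Simulation of Sugar-Sweetened Beverage Taxation Effects on Adult Obesity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative risk assessment model of the effect of a
    sugar-sweetened beverage (SSB) tax on adult obesity prevalence.
    Categorical beverage-consumption survey responses are converted to daily
    volumes by midpoint imputation, a tax-induced price rise is propagated
    through own- and cross-price elasticities to volume and energy-intake
    changes, an equilibrium energy-balance factor converts energy to body
    weight and BMI shifts, and counterfactual obesity prevalence follows from
    shifting fitted lognormal (or gamma) population BMI distributions.
    Includes a synthetic survey-data generator, Monte Carlo uncertainty
    propagation, two-way tax/pass-on sensitivity analysis and a serving-size
    tornado analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
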
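Package: kintox
Title: Kinetic Modelling and Evolving Toxicity of Catalytic Micropollutant Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the oxidative degradation of micropollutants by
    peroxide-activating iron catalysts. Builds mass-action reaction networks for
    a two-step catalytic cycle (activation by hydrogen peroxide, substrate
    oxidation, first-order operational inactivation) combined with direct
    peroxide oxidations, integrates the resulting stiff ODE systems, estimates
    rate constants from concentration-time data (initial-rate hyperbolic fits,
    pseudo-first-order analysis, and a global network fit), and converts
    simulated concentration profiles into composite toxic-unit profiles from
    LC50 tables. A propranolol degradation cascade is included as a built-in
    example network, together with a synthetic chromatography-style observation
    generator for end-to-end testing of the fitting and profiling pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
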
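Package: ecocap
Title: Multispecies Age-Structured Food-Web Simulation for Ecosystem
    Catch-Cap Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, deterministic multispecies age-structured
    food-web simulator with climate-linked consumption, habitat
    suitability, and temperature-gated recruitment, built to evaluate
    ecosystem-level ("optimum yield") caps on aggregate fishery catch.
    Provides a two-step fishing-mortality experiment (per-stock F_MSY
    profiling, then multispecies MF_MSY multipliers under climate and
    predator-exploitation scenarios), delta bias correction and looped
    daily climatologies for climate forcing, and evaluation metrics
    comparing aggregate equilibrium yield against a catch cap,
    counting stocks below the B35% overfishing reference point, and
    quantifying indirect food-web effects on forage fish and
    piscivorous predators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
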
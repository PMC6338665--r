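Package: otoFMR
Title: Field Metabolic Rate Estimation from Otolith Carbon Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates field metabolic rate (FMR) of teleost fishes from the
    stable carbon isotope composition of otolith aragonite. Implements the
    two-endmember mixing model for the proportion of metabolically derived
    carbon (M_oto), oxygen-isotope thermometry, metabolic-theory-of-ecology
    (Boltzmann-Arrhenius) standard metabolic rate models, the saturating
    calibration between M_oto and oxygen consumption with Monte Carlo
    errors-in-variables uncertainty, power-budget validation tests,
    AIC-profiled allometric exponent estimation, and two-sample power
    analysis for study design. Includes synthetic-data generators that
    emulate a temperature-controlled rearing experiment, a wild population
    and a multi-species compilation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
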
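Package: ointchar
Title: Physicochemical Characterization of Semi-Solid Dosage Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for the bench characterization of ointments and
    creams: parallel-plate spreadability curves with a log-law fit, area under
    the spread curve and a spreadability index against a reference base;
    rotational rheology with step-rate viscosity summaries, yield-stress
    (Bingham/Casson) flow-curve fits and thixotropy quantified as the
    hysteresis-loop area between ascending and descending ramps; texture
    profile analysis (TPA) of two-cycle compression traces yielding hardness,
    cohesiveness, adhesiveness, elasticity and adhesion force, plus tensile
    strength and Young's modulus; and in-vitro release testing through an
    enhancer cell with UV calibration, withdrawal/replacement mass-balance
    correction and a five-model kinetic suite (zero-order, first-order,
    Higuchi, Korsmeyer-Peppas, Weibull). Deterministic synthetic-instrument
    generators with ground-truth sidecars support end-to-end parameter-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
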
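Package: necsim
Title: Mean-Field Simulation of Cocaine-Induced Noradrenaline Release in a
    Four-Region Brain Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates noradrenaline (NE) dynamics in a four-region
    mean-field circuit (locus coeruleus, medial prefrontal cortex, nucleus
    of the tractus solitarius, nucleus accumbens shell) driven by a
    pharmacodynamic cocaine kernel. Provides fixed-step integration of the
    six-equation linear ODE system with a prefrontal NE-depletion switch,
    genetic-algorithm fitting of the seventeen circuit coefficients to
    steady-state firing and concentration targets, closed-form linear
    stability analysis (equilibria, eigenvalue spectra, kernel sweeps),
    a virtual microdialysis experiment over cohorts of simulated mice,
    and the accompanying statistical pipeline (normality screening,
    two-sample test selection, repeated-measures ANOVA with Sidak
    correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
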
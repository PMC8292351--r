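Package: cytb6f
Title: Steady-State C3 Photosynthesis with Cytochrome b6f as a Regulated
    Conductance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic model of steady-state electron transport and CO2
    assimilation in C3 leaves in which the Cytochrome b6f complex acts as a
    regulated conductance coupling photosystem II and photosystem I to
    Rubisco. Provides the coupled ATP/NADPH/Fd budgets linking linear and
    cyclic electron flow to carbon metabolism, rate equations for Cyt b6f,
    PS I and PS II with exciton sharing and regulated heat dissipation, a
    minimum-rule solver for the b6f-limited and Rubisco-limited regimes, a
    forward operator from solved states to pulse-amplitude modulated (PAM)
    fluorescence levels and quenching indices (qP, qL, NPQ, kLake), the CO2
    diffusion path from cuvette air to chloroplast, a synthetic light
    sine-wave protocol generator, and a multiobjective (NSGA-II) inversion
    that fits the model to paired fluorescence and gas-exchange series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
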
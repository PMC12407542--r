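Package: rafpa
Title: Equilibrium Models of RAF Paradoxical Activation and Its Modulation by 14-3-3
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Closed-form and brute-force equilibrium models of RAF kinase
    activation under ATP-competitive inhibition, covering conformational
    autoinhibition, RAF dimerization, drug binding, and the two binding roles
    of dimeric 14-3-3 proteins: stabilization of the autoinhibited monomer
    (CAS) and stabilization of the active dimer (DS). Provides analytic
    steady-state solutions and paradoxical-activation (PA) conditions for the
    four model variants, a mass-action equilibrium solver built on detailed
    balance and conservation of total RAF, drug and 14-3-3, dose-response
    simulation with PA fold-change and PA-range (crossover dose) metrics,
    two-parameter sweep grids, and a synthetic saturable-readout generator
    with bootstrap estimation of PA metrics from noisy replicates.
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
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
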
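Package: lanmm
Title: Laminar Neural Mass Model: Simulation, Bifurcation and
    Cross-Frequency Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a five-population laminar neural mass model that
    couples a Jansen-Rit circuit (deep cortical layers, slow rhythms) with
    a pyramidal-interneuron gamma (PING) circuit (superficial layers).
    Provides deterministic simulation with compiled dynamics, equilibrium
    and limit-cycle continuation with fold/SNIC/Hopf/torus/period-doubling
    detection, Floquet multipliers via the monodromy matrix, Benettin
    Lyapunov exponents with regime classification, Welch spectra with
    dominant-frequency maps, phase-amplitude coupling via the Tort
    modulation index, a parvalbumin-dysfunction scenario, and a two-column
    long-range coupling extension, together with synthetic generators with
    known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
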
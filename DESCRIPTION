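Package: gassr
Title: Gamma-Band Auditory Steady-State Response Analysis with Synthetic EEG
    and Crossover Dose Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses gamma-band auditory steady-state response
    (ASSR) experiments of the kind used to demonstrate NMDA-receptor target
    engagement in crossover drug trials. Provides a synthetic-data module
    (click-train stimulus design, colored-noise EEG with von Mises
    phase-locked steady-state entrainment, one-compartment oral
    pharmacokinetic metabolite curves), EDF and feature-table input/output,
    epoching and artifact rejection, Morlet time-frequency analysis with
    evoked power and inter-trial phase coherence, Welch resting spectra with
    band power and aperiodic 1/f slope estimation, and linear mixed-effect
    dose-contrast statistics for three-period crossover designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
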
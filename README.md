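# gassr

Gamma-band auditory steady-state response (ASSR) analysis for crossover
dose-finding studies, with a fully synthetic data path.

## What this is for

Blocking NMDA receptors on cortical fast-spiking interneurons disinhibits
gamma-band circuits, so gamma EEG measures — the 40 Hz ASSR evoked power,
its inter-trial phase coherence (ITPC), resting gamma power and the
aperiodic 1/f spectral slope — serve as pharmacodynamic markers of brain
target engagement in early-phase drug trials. The typical design is a
three-period crossover: each subject receives placebo, a low and a high
dose on separate days; EEG and plasma metabolites are measured before
dosing and hourly afterwards; and dose contrasts are estimated per measure
with a linear mixed model.

`gassr` implements that workflow end to end for methodologists and
trial analysts:

* **synthetic data** — click-train stimulus design (500 ms trains of 1 ms
  clicks at 20/30/40 Hz, 110 trials/block, oddballs, 3 s ITI), multichannel
  EEG with `1/f^chi` colored noise and von Mises phase-locked entrainment,
  alternating eyes-closed/eyes-open resting runs, and Bateman
  one-compartment metabolite curves (tmax ≈ 1 h, half-life 1.75 h);
* **I/O** — EDF recordings with a tab-separated events sidecar; validated
  long-format feature tables in CSV; YAML/JSON pipeline configs;
* **preprocessing** — zero-phase band-pass, average reference, index-exact
  epoching with oddball exclusion, peak-to-peak artifact rejection;
* **features** — Morlet time-frequency analysis, ITPC
  (`|mean(coeff/|coeff|)|`, Rayleigh null `sqrt(pi)/(2 sqrt(N))`),
  baseline-corrected evoked power, Welch spectra, gamma band power in dB,
  and the OLS log-log aperiodic slope;
* **statistics** — per measure, the crossover LMM
  `value ~ dose + time + baseline + (1 | subject)` fitted by REML with
  Satterthwaite degrees of freedom, omnibus dose F, and low/high-vs-placebo
  contrasts with 95% CIs, summarized into a results table.

## Worked example

Simulate a 10-subject crossover at the default calibration (placebo 40 Hz
ITPC ≈ 0.18, a high-dose-only shift of +0.02) and fit the dose model:

```r
library(gassr)
tab <- simulate_feature_study(n_subjects = 10, rng_seed = 7)
dose_model(tab, "assr40_itpc")
#> <dose_model_result> assr40_itpc: F(2, 106.6) = 4.83, p = 0.009824 [satterthwaite df]
#>         contrast   estimate          se       df        t           p    ci_lower   ci_upper
#>   low_vs_placebo 0.00302603 0.006937827 107.7874 0.436164 0.663590123 -0.01072625 0.01677831
#>  high_vs_placebo 0.01904290 0.006516424 104.1503 2.922294 0.004262005  0.00612081 0.03196500
```

The high dose separates from placebo (t = 2.92, CI excluding zero) while
the low dose does not — the qualitative signature of dose-limited target
engagement. For the full EEG path, `run_demo("demo_out", seed = 1)`
simulates a reduced study (4 subjects, 30 trials/block) to EDF, extracts
all eight EEG measures plus seven metabolites, fits every model and writes
`features.csv`, `report.csv`/`report.json` and summary figures, in about
two minutes.

A command-line wrapper with `simulate` / `analyze` / `report` / `demo`
subcommands is installed at `inst/cli/gassr.R`.

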
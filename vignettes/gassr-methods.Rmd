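---
title: "Methods: simulating and analysing gamma-band ASSR dose studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing gamma-band ASSR dose studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

NMDA-receptor antagonists disinhibit cortical gamma-band circuits: blocking
NMDARs on fast-spiking interneurons increases both spontaneous gamma power
and the entrained 40 Hz auditory steady-state response (ASSR). This makes
gamma-band EEG a pharmacodynamic readout of brain target engagement in
early-phase crossover trials: each subject receives placebo, a low and a
high dose on separate days, EEG and plasma are sampled before dosing and
hourly afterwards, and dose contrasts are estimated with linear mixed
models. `gassr` implements that entire workflow — stimulus design, EEG and
pharmacokinetic simulation, feature extraction, and the crossover
statistics — so the analysis chain can be developed and validated without
access to human recordings.

# The synthetic-data generator

The generator's role is to emulate the *structure* of such a study, with
enough physiological realism that every downstream estimator has a known
ground truth.

**Stimulus.** Click trains of 500 ms built from 1 ms clicks repeated at
20/30/40 Hz, 110 standard trials per block (one block per rate), eleven
2000 Hz-carrier oddball trains interleaved per session for attention
monitoring, inter-trial interval 3 s. At EEG sampling rates the carrier
tone is unresolvable, so oddballs differ from standards only by their event
label; they are excluded from analysis, as is conventional.

**EEG model.** No published generative model exists for these recordings,
so the simulator uses the simplest model under which the outcome measures
have closed-form or Monte-Carlo oracles:

* background: independent per-channel colored noise with power spectral
  density proportional to `1/f^chi` (default `chi = 1`, SD 10 µV),
  generated by spectral shaping of white noise;
* a 10 Hz alpha rhythm (8 µV) on posterior channels, attenuated to 30%
  with eyes open;
* during each trial's 0–0.5 s window, a sinusoid at the stimulation rate
  on the fronto-central channels whose per-trial phase is drawn from a
  von Mises distribution with concentration `kappa` — evoked power is then
  controlled by the amplitude and inter-trial phase coherence (ITPC)
  jointly by amplitude and `kappa`;
* blink transients (Gaussian bumps, 120 µV, 4/min) on frontal channels,
  60 Hz mains at 1 µV, and a broadband noise increase (factor 1.3) with
  eyes open;
* a resting run of alternating 1-min eyes-closed/eyes-open segments
  (two cycles), with a band-limited 30–50 Hz component whose amplitude is
  dose dependent — the simulator's resting gamma effect.

The montage is a reduced 8-channel set (Fz, FCz, Cz, CPz, Pz, F3, F4, Oz)
covering the fronto-central ASSR maximum and the posterior alpha
generators; 64-channel forward modelling is deliberately out of scope.
The sampling rate defaults to 500 Hz, which resolves the gamma band with
margin.

**Dose conditions.** Dose acts only through the 40 Hz condition
(`dose_rates = 40`): amplitude 2.1 µV and `kappa` 0.78 under placebo and
low dose, 2.7 µV and `kappa` 0.70 under the high dose, plus the resting
gamma amplitudes 1.0/1.0/1.3 µV. These values were calibrated once (24
simulated recordings per candidate) so that the full analysis chain lands
near an ITPC of 0.18 under placebo and 0.20 under the high dose at 110
trials — the levels reported for this class of study — and encode a
high-dose-only drug effect. The drug raises amplitude strongly while
slightly loosening phase concentration, so evoked power rises much more
than ITPC — matching the observation that such drugs inflate gamma power
by tens of percent while ITPC moves by only ~10%. The low dose is
identical to placebo by construction, which gives the statistics stage a
true negative to report.

**Crossover design.** Each subject's first-week dose is randomized; the
remaining weeks follow a fixed rotation (high → placebo → low;
low → high → placebo; placebo → low → high), so every subject receives
each condition exactly once.

**Pharmacokinetics.** Plasma metabolites follow a Bateman (one-compartment,
first-order absorption/elimination) curve
`C(t) = baseline·(1 + diurnal) + scale·dose·ka/(ka−ke)·(e^{−ke t} − e^{−ka t})`
with `ka = 2.0/h` and `ke = ln 2 / 1.75 /h`, placing the peak at
`tmax = ln(ka/ke)/(ka−ke) ≈ 1.01 h` and the half-life at 1.75 h — inside
the 1–2 h and 1.5–2 h windows established for the oral prodrug. Placebo
sessions show the baseline plus a configurable cosine diurnal drift;
measurement noise is multiplicative log-normal (CV 10%). The analyte panel
distinguishes dose-responsive species (the prodrug and its products, KYNA,
3-HAA) from endogenous metabolites held at baseline (KYN, QUIN).

# Feature extraction

Defaults follow conventional ASSR practice and are all configurable;
published studies rarely specify their preprocessing completely, so the
package declares every choice explicitly:

* zero-phase Butterworth band-pass 1–80 Hz (order 4 per pass, high- and
  low-pass applied separately for numerical robustness), average reference;
* epochs −0.5 to 1.0 s around train onset; peak-to-peak rejection at
  150 µV; no ICA or ocular regression — blink handling is by rejection
  only, which keeps the chain deterministic;
* Morlet wavelets (7 cycles) on the scoring band (rate ± 2 Hz); kernels
  are amplitude-normalized so a sinusoid of amplitude A yields |coeff| = A.
  Scoring window 0.1–0.5 s (the steady-state portion), ROI Fz/FCz/Cz;
* evoked power is baseline-corrected per channel and frequency against
  the −0.4 to −0.1 s pre-stimulus mean, as relative change by default
  (dB optional). Whether such "power" outcomes should be corrected
  within-epoch, against the pretreatment session, or both is ambiguous in
  this literature; within-epoch correction is the default here and the
  pretreatment session enters the statistics as a covariate instead;
* ITPC is the magnitude of the mean unit phase vector across retained
  trials; under uniform phases its expectation is the Rayleigh null
  `sqrt(pi)/(2 sqrt(N))` (0.085 at N = 110), which the test suite verifies
  by Monte Carlo;
* resting spectra by Welch's method (2 s Hamming windows, 50% overlap),
  eyes-closed and eyes-open averaged with equal weight; gamma power is the
  30–50 Hz band integral in dB with a 58–62 Hz mains notch excluded;
* the aperiodic 1/f exponent is the OLS slope of log10 power on log10
  frequency over 3–40 Hz excluding 6–14 Hz (theta/alpha peaks), requiring
  at least 10 frequency points. A plain OLS fit was chosen over a
  peak-parameterized spectral model as the simplest defensible estimator;
  the exclusion bands make it robust to the alpha peak, which the tests
  check explicitly.

# The statistics stage

For each measure the model is the standard crossover LMM: dose (3 levels,
placebo reference) as fixed effect, time and the session's pretreatment
baseline as covariates, and a random intercept per subject. EEG measures
use hours 1–4 post-dose (the fifth hour is conventionally discarded as too
noisy); metabolites and vitals use hours 1–5. Estimation is REML via
`lme4`, with Satterthwaite degrees of freedom (`lmerTest`) — the default
of SPSS MIXED, which this class of study typically uses — and
low-vs-placebo / high-vs-placebo contrasts with 95% CIs from `emmeans`
(no multiplicity adjustment by default, matching per-measure reporting;
Benjamini–Hochberg is available). Time is categorical by default (the
linear coding is a config switch) since nothing in the source designs
constrains it. Non-convergence and singular fits are warned about, never
silent.

**Operating characteristics.** The feature-level simulator
(`simulate_feature_study`) generates measurement tables directly from a
generative model under which this LMM is *correctly specified*: each
session's baseline is `mu + trait + day-state`, and post-dose values couple
to the *measured* baseline with a single regression-to-the-mean coefficient
(0.6), plus an independent post-dose subject intercept and iid noise. Two
subtleties matter and were found the hard way: (i) if the day-state that
the baseline records does not carry into the post-dose hours, or carries
independently of the measurement, rows within a session are correlated
beyond the subject intercept and the omnibus F is anticonservative;
(ii) if the subject trait appears in both the covariate and the random
intercept, the covariate is endogenous and the test inflates similarly.
The chosen generator avoids both by construction, and the acceptance suite
confirms a type-I error of 5% ± 2% over 500 null replicates at n = 10
subjects, with ≥ 80% power for the default high-dose-only shift of +0.02
ITPC units (observed ≈ 95%) over 100 replicates.

# Problem sizes and determinism

Every random quantity is driven by a single integer seed; per-recording
and per-series seeds are derived deterministically from it, and a
simulated dataset reproduces bit-for-bit (verified by manifest MD5s).
The bundled demonstration (`run_demo`) uses 4 subjects, 30 standard trials
per block, 250 Hz, 30 s resting segments and EEG at baseline plus hours
1–4 — about two minutes of compute — while module-level validation uses the
full 110-trial, 500 Hz conditions. Monte-Carlo validation sizes (100
spectral realizations per exponent, 500 null model fits, 1000-replicate
Rayleigh oracle) were chosen so Monte-Carlo error sits well below each
tolerance.

# What passing tests do and do not show

The simulator reproduces the *design* of such studies (trial counts,
timing, crossover rotation, kinetic windows, effect topology) and enough
signal structure to validate the estimators against ground truth. It does
not reproduce volume conduction from 64-channel recordings, non-stationary
artifacts (movement, electrode drift), heavy-tailed noise, or the true
coupling between plasma kinetics and the EEG response (the simulated EEG
dose effect is constant over the post-dose hours, while real drug effects
wax and wane with concentration). Green tests therefore certify the
correctness of the computations, not that real recordings would yield any
particular result. Reproducing the numerical dose-contrast estimates of
any specific human study is explicitly out of scope: those depend on
recordings that are not public.

# Known limitations

* EDF support covers the uniform-rate 16-bit layout this package writes;
  signals with per-channel rates are rejected rather than resampled.
* The peak-to-peak rejector is the only artifact defence; datasets with
  dense blinks need the threshold tuned or cleaner simulation settings.
* The 1/f slope estimator is a plain OLS fit; spectra with strong
  oscillatory peaks outside the default exclusion bands will bias it.
* `fit_dose_model` assumes the placebo/low/high labelling; other designs
  need their own contrast specification.
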
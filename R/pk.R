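#' One-compartment oral pharmacokinetic configuration
#'
#' Parameters of the Bateman (first-order absorption and elimination)
#' concentration curve used to emulate plasma metabolite trajectories.
#' Defaults place the peak (tmax = log(ka/ke)/(ka - ke)) near 1 h and the
#' elimination half-life (log(2)/ke) at 1.75 h, inside the 1-2 h tmax and
#' 1.5-2 h half-life windows reported for the oral prodrug across doses.
#'
#' @param ka Absorption rate constant, /h. Must exceed `ke`.
#' @param ke Elimination rate constant, /h (> 0).
#' @param scale Peak-determining factor: the Bateman component is
#'   `scale * dose_mg * ka/(ka - ke) * (exp(-ke t) - exp(-ka t))`, ng/mL
#'   per mg.
#' @param baseline Endogenous concentration, ng/mL (>= 0).
#' @param diurnal_amplitude Fractional amplitude of a cosine diurnal
#'   modulation of the baseline.
#' @param diurnal_period Diurnal period, hours.
#' @param diurnal_phase Phase of the diurnal cosine at t = 0, radians.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise (>= 0).
#'
#' @return An object of class `pk_config`.
#' @export
pk_config <- function(ka = 2.0, ke = log(2) / 1.75, scale = 0.1,
                      baseline = 5, diurnal_amplitude = 0.1,
                      diurnal_period = 24, diurnal_phase = 0,
                      noise_cv = 0.1) {
  if (ka == ke) stop("ka must differ from ke (degenerate Bateman curve)")
  if (!(ka > ke) || ke <= 0) stop("require ka > ke > 0 for a non-degenerate curve")
  if (baseline < 0) stop("baseline must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(ka = ka, ke = ke, scale = scale, baseline = baseline,
                 diurnal_amplitude = diurnal_amplitude,
                 diurnal_period = diurnal_period,
                 diurnal_phase = diurnal_phase, noise_cv = noise_cv),
            class = "pk_config")
}

#' Noiseless Bateman concentration curve
#'
#' `C(t) = baseline * (1 + diurnal(t)) +
#'   scale * dose_mg * ka/(ka-ke) * (exp(-ke t) - exp(-ka t))`.
#' Placebo (`dose_mg = 0`) yields the baseline plus diurnal term only; the
#' drug component is linear in dose.
#'
#' @param times Hours post-dose.
#' @param dose_mg Administered dose, mg (>= 0).
#' @param pk A [pk_config()].
#' @return Concentrations, ng/mL.
#' @export
bateman_curve <- function(times, dose_mg, pk = pk_config()) {
  stopifnot(dose_mg >= 0)
  diurnal <- pk$diurnal_amplitude *
    cos(2 * pi * times / pk$diurnal_period + pk$diurnal_phase)
  drug <- pk$scale * dose_mg * pk$ka / (pk$ka - pk$ke) *
    (exp(-pk$ke * times) - exp(-pk$ka * times))
  pk$baseline * (1 + diurnal) + drug
}

#' Closed-form time of peak concentration
#' @param pk A [pk_config()].
#' @return tmax in hours, `log(ka/ke)/(ka - ke)`.
#' @export
pk_tmax <- function(pk) log(pk$ka / pk$ke) / (pk$ka - pk$ke)

#' Closed-form elimination half-life
#' @param pk A [pk_config()].
#' @return Half-life in hours, `log(2)/ke`.
#' @export
pk_half_life <- function(pk) log(2) / pk$ke

#' Simulate a metabolite concentration series
#'
#' Evaluates the Bateman curve at the requested times and applies
#' multiplicative log-normal measurement noise with coefficient of
#' variation `noise_cv`. Concentrations that would fall below zero are
#' clipped at zero (with a message).
#'
#' @param analyte Analyte label (e.g. `"7-Cl-KYNA"`, `"KYNA"`).
#' @param dose_mg Administered dose, mg.
#' @param pk A [pk_config()].
#' @param times Hours post-dose, strictly increasing, within [0, 24].
#' @param rng_seed Integer seed for the measurement noise.
#'
#' @return A data frame of class `metabolite_series` with columns
#'   `analyte`, `time`, `concentration`.
#' @export
simulate_metabolite <- function(analyte, dose_mg, pk = pk_config(),
                                times = 0:5, rng_seed = 1L) {
  if (any(times < 0 | times > 24)) stop("times must lie within [0, 24] hours")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  set.seed(as.integer(rng_seed))
  conc <- bateman_curve(times, dose_mg, pk)
  if (pk$noise_cv > 0) {
    sdlog <- sqrt(log(1 + pk$noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  if (any(conc < 0)) {
    message("simulate_metabolite: clipping ", sum(conc < 0), " negative concentration(s) at 0")
    conc <- pmax(conc, 0)
  }
  structure(data.frame(analyte = analyte, time = times, concentration = conc),
            class = c("metabolite_series", "data.frame"))
}

#' Default analyte panel
#'
#' The kynurenine-pathway analytes tracked by the pipeline with per-analyte
#' dose responsiveness: the prodrug and its products rise with dose, the
#' endogenous metabolites KYN and QUIN do not.
#'
#' @return Data frame with `analyte`, `scale` (ng/mL per mg), `baseline`
#'   (ng/mL), `dose_responsive` (logical).
#' @export
analyte_panel <- function() {
  data.frame(
    analyte = c("4-Cl-KYN", "7-Cl-KYNA", "4-Cl-3-HAA", "KYN", "KYNA", "3-HAA", "QUIN"),
    scale = c(15, 0.12, 0.012, 0, 0.004, 0.002, 0),
    baseline = c(0.5, 1, 1, 300, 6, 3.3, 47),
    dose_responsive = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}
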
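#' Three-period crossover design with rotation-rule dose sequences
#'
#' Builds the session table for a placebo / low (720 mg) / high (1440 mg)
#' crossover: each subject's week-1 dose is randomized, and weeks 2-3 then
#' follow a fixed rotation — high is followed by placebo then low; low by
#' high then placebo; placebo by low then high. Every subject therefore
#' receives each dose exactly once.
#'
#' @param n_subjects Number of subjects.
#' @param timepoints Ordered within-session measurement labels; the first is
#'   the pretreatment baseline.
#' @param rng_seed Integer seed for the week-1 randomization.
#'
#' @return A data frame of class `session_design` with columns `subject_id`,
#'   `visit` (1-3), `dose` (factor placebo/low/high, placebo reference),
#'   and `dose_mg` (0/720/1440).
#' @examples
#' d <- crossover_design(10, rng_seed = 1)
#' table(d$subject_id, d$dose)  # all ones
#' @export
crossover_design <- function(n_subjects = 10,
                             timepoints = c("baseline", "h1", "h2", "h3", "h4", "h5"),
                             rng_seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(as.integer(rng_seed))
  doses <- c("placebo", "low", "high")
  rotation <- list(high    = c("high", "placebo", "low"),
                   low     = c("low", "high", "placebo"),
                   placebo = c("placebo", "low", "high"))
  first <- sample(doses, n_subjects, replace = TRUE)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject_id = sprintf("S%02d", s), visit = 1:3,
               dose = rotation[[first[s]]])
  }))
  out$dose <- factor(out$dose, levels = doses)
  out$dose_mg <- c(placebo = 0, low = 720, high = 1440)[as.character(out$dose)]
  attr(out, "timepoints") <- timepoints
  class(out) <- c("session_design", "data.frame")
  out
}

#' Synthetic EEG effect configuration
#'
#' Generative parameters of the synthetic recordings: a 1/f^chi colored-noise
#' background, a posterior alpha rhythm (stronger with eyes closed), mains
#' line noise, frontal blink transients, and — during each ASSR trial — a
#' sinusoid at the stimulation rate whose per-trial phase is drawn from a
#' von Mises distribution. Dose conditions differ only through
#' `ssr_amplitude` and `phase_concentration`, and only at the rates listed
#' in `dose_rates` (other rates use the placebo values), emulating a
#' drug effect confined to 40 Hz entrainment.
#'
#' Defaults are calibrated so that, through the default analysis chain
#' (110 trials, fronto-central ROI), the 40 Hz ITPC score lands near 0.18
#' under placebo and near 0.20 under the high dose. The high dose raises
#' the amplitude markedly and loosens phase concentration slightly —
#' evoked power rises much more than ITPC, the typical pattern for
#' NMDAR-antagonist gamma enhancement.
#'
#' @param noise_exponent Background spectral exponent chi (>= 0).
#' @param noise_scale Background noise SD, microvolts.
#' @param ssr_amplitude Named numeric, steady-state amplitude in microvolts
#'   per dose condition (placebo/low/high).
#' @param phase_concentration Named numeric, von Mises concentration kappa
#'   (>= 0) per dose condition.
#' @param dose_rates Stimulation rates (Hz) at which the dose-specific
#'   amplitude/kappa apply; other rates use the placebo values.
#' @param resting_gamma_amplitude Named numeric, SD in microvolts of
#'   band-limited (30-50 Hz) noise added to all channels during resting
#'   segments, per dose condition — the simulator's resting gamma-power
#'   dose effect.
#' @param alpha_amplitude Alpha-rhythm amplitude, microvolts (eyes-closed;
#'   eyes-open alpha is attenuated by `alpha_eo_factor`).
#' @param alpha_eo_factor Multiplier on alpha amplitude with eyes open.
#' @param eo_noise_factor Multiplier on broadband noise SD with eyes open.
#' @param blink_rate Blink transients per minute on frontal channels.
#' @param blink_amplitude Blink peak amplitude, microvolts.
#' @param line_noise_amplitude Mains (60 Hz) amplitude, microvolts.
#'
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(noise_exponent = 1.0,
                          noise_scale = 10,
                          ssr_amplitude = c(placebo = 2.1, low = 2.1, high = 2.7),
                          phase_concentration = c(placebo = 0.78, low = 0.78, high = 0.7),
                          dose_rates = 40,
                          resting_gamma_amplitude = c(placebo = 1, low = 1, high = 1.3),
                          alpha_amplitude = 8,
                          alpha_eo_factor = 0.3,
                          eo_noise_factor = 1.3,
                          blink_rate = 4,
                          blink_amplitude = 120,
                          line_noise_amplitude = 1) {
  stopifnot(noise_exponent >= 0, noise_scale >= 0,
            all(ssr_amplitude >= 0), all(phase_concentration >= 0),
            alpha_amplitude >= 0, blink_rate >= 0, line_noise_amplitude >= 0)
  need <- c("placebo", "low", "high")
  if (!all(need %in% names(ssr_amplitude)) ||
      !all(need %in% names(phase_concentration)) ||
      !all(need %in% names(resting_gamma_amplitude))) {
    stop("per-dose parameters need named entries placebo/low/high")
  }
  stopifnot(all(resting_gamma_amplitude >= 0))
  structure(list(noise_exponent = noise_exponent, noise_scale = noise_scale,
                 ssr_amplitude = ssr_amplitude,
                 phase_concentration = phase_concentration,
                 dose_rates = dose_rates,
                 resting_gamma_amplitude = resting_gamma_amplitude,
                 alpha_amplitude = alpha_amplitude,
                 alpha_eo_factor = alpha_eo_factor,
                 eo_noise_factor = eo_noise_factor,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 line_noise_amplitude = line_noise_amplitude),
            class = "effect_config")
}

# Channel montage used by the simulator (reduced fronto-central + posterior set)
gassr_montage <- function() {
  list(labels = c("Fz", "FCz", "Cz", "CPz", "Pz", "F3", "F4", "Oz"),
       assr = c("Fz", "FCz", "Cz", "CPz"),     # channels carrying entrainment
       frontal = c("Fz", "F3", "F4"),          # blink-loaded channels
       posterior = c("CPz", "Pz", "Oz"),       # alpha-loaded channels
       roi = c("Fz", "FCz", "Cz"))             # default scoring ROI
}

#' Simulate one session-timepoint EEG recording
#'
#' Produces a continuous multi-channel recording containing the session's
#' ASSR blocks (one block per rate in `rates`, standards plus interleaved
#' oddballs) followed by a resting run of alternating eyes-closed/eyes-open
#' segments. During each trial's 0 to `train_duration` window a sinusoid at
#' the trial's repetition rate is added to the fronto-central channels with
#' amplitude `ssr_amplitude[dose]` and a per-trial phase drawn von
#' Mises(0, `phase_concentration[dose]`). Every trial onset and resting
#' segment start is embedded as an event marker.
#'
#' @param dose Dose condition of the session (`"placebo"`, `"low"`, `"high"`).
#' @param effect An [effect_config()].
#' @param spec A [click_train_spec()].
#' @param fs Sampling rate, Hz (>= 250 so the gamma band is resolvable).
#' @param rates Repetition rates of the ASSR blocks, Hz.
#' @param rest_segment_s Duration of each resting segment, seconds.
#' @param n_rest_cycles Number of eyes-closed/eyes-open alternation cycles
#'   (2 cycles = 2 EC + 2 EO segments).
#' @param rng_seed Integer seed; fixed seed + config gives a bit-identical
#'   recording.
#'
#' @return An `eeg_recording` (see [eeg_recording()]) with events coded
#'   `assr<rate>`, `oddball<rate>`, `EC`, `EO`.
#' @export
simulate_recording <- function(dose, effect = effect_config(),
                               spec = click_train_spec(), fs = 500,
                               rates = c(40, 30, 20),
                               rest_segment_s = 60, n_rest_cycles = 2,
                               rng_seed = 1L) {
  if (!dose %in% c("placebo", "low", "high")) {
    stop("unknown dose condition: ", dose)
  }
  if (fs < 250) stop("fs must be >= 250 Hz to resolve the gamma band")
  set.seed(as.integer(rng_seed))
  mon <- gassr_montage()
  n_ch <- length(mon$labels)
  soa <- spec$train_duration + spec$iti

  seq_tab <- make_block_sequence(spec, rates = rates,
                                 rng_seed = sample.int(.Machine$integer.max, 1))
  n_per_block <- as.vector(table(factor(seq_tab$block, levels = seq_along(rates))))
  block_len_s <- n_per_block * soa
  block_start_s <- cumsum(c(0, utils::head(block_len_s, -1)))
  assr_len_s <- sum(block_len_s)
  rest_len_s <- 2 * n_rest_cycles * rest_segment_s
  n_samp <- round((assr_len_s + rest_len_s) * fs)

  # absolute trial onsets
  seq_tab$onset_s <- block_start_s[seq_tab$block] + seq_tab$onset
  seq_tab$onset_sample <- round(seq_tab$onset_s * fs)

  # background: independent colored noise per channel
  data <- matrix(0, n_ch, n_samp)
  for (c in seq_len(n_ch)) {
    data[c, ] <- colored_noise(n_samp, fs, effect$noise_exponent) * effect$noise_scale
  }

  tvec <- seq(0, n_samp - 1) / fs
  rest_start_s <- assr_len_s
  eo_mask <- rep(FALSE, n_samp)   # samples with eyes open
  rest_events <- NULL
  for (cyc in seq_len(n_rest_cycles)) {
    ec0 <- rest_start_s + (cyc - 1) * 2 * rest_segment_s
    eo0 <- ec0 + rest_segment_s
    eo_idx <- which(tvec >= eo0 & tvec < eo0 + rest_segment_s)
    eo_mask[eo_idx] <- TRUE
    rest_events <- rbind(rest_events,
                         data.frame(onset_sample = round(c(ec0, eo0) * fs),
                                    duration = round(rest_segment_s * fs),
                                    code = c("EC", "EO")))
  }
  # eyes-open: broader-band noise (extra white noise on all channels)
  if (effect$eo_noise_factor > 1 && any(eo_mask)) {
    extra_sd <- effect$noise_scale * sqrt(effect$eo_noise_factor^2 - 1)
    n_eo <- sum(eo_mask)
    for (c in seq_len(n_ch)) {
      data[c, eo_mask] <- data[c, eo_mask] + stats::rnorm(n_eo, sd = extra_sd)
    }
  }

  # resting gamma-band component, dose dependent (the resting drug effect)
  g_amp <- effect$resting_gamma_amplitude[[dose]]
  if (g_amp > 0) {
    rest_idx <- which(tvec >= rest_start_s)
    if (length(rest_idx) > 1) {
      for (c in seq_len(n_ch)) {
        data[c, rest_idx] <- data[c, rest_idx] +
          g_amp * band_noise(length(rest_idx), fs, 30, 50)
      }
    }
  }

  # alpha rhythm on posterior channels, attenuated with eyes open
  alpha_phase <- stats::runif(1, 0, 2 * pi)
  alpha <- sin(2 * pi * 10 * tvec + alpha_phase)
  alpha_gain <- ifelse(eo_mask, effect$alpha_eo_factor, 1)
  # during ASSR blocks eyes are open (task): use EO alpha level there
  alpha_gain[tvec < rest_start_s] <- effect$alpha_eo_factor
  for (ch in mon$posterior) {
    c <- match(ch, mon$labels)
    data[c, ] <- data[c, ] + effect$alpha_amplitude * alpha * alpha_gain
  }

  # steady-state response on fronto-central channels, standard trials only
  amp_tab <- effect$ssr_amplitude
  kap_tab <- effect$phase_concentration
  train_n <- round(spec$train_duration * fs)
  assr_rows <- match(mon$assr, mon$labels)
  for (i in seq_len(nrow(seq_tab))) {
    tr <- seq_tab[i, ]
    dosed <- tr$rate %in% effect$dose_rates
    amp <- if (dosed) amp_tab[[dose]] else amp_tab[["placebo"]]
    kap <- if (dosed) kap_tab[[dose]] else kap_tab[["placebo"]]
    phi <- rvonmises(1, 0, kap)
    idx <- tr$onset_sample + seq_len(train_n)   # samples [onset, onset+train)
    tt <- (seq_len(train_n) - 1) / fs
    wave <- amp * sin(2 * pi * tr$rate * tt + phi)
    data[assr_rows, idx] <- sweep(data[assr_rows, idx, drop = FALSE], 2, wave, `+`)
  }

  # blink transients on frontal channels
  if (effect$blink_rate > 0 && effect$blink_amplitude > 0) {
    n_blinks <- stats::rpois(1, effect$blink_rate * n_samp / fs / 60)
    if (n_blinks > 0) {
      blink_t <- sort(stats::runif(n_blinks, 0.5, n_samp / fs - 0.5))
      blink_shape <- exp(-((seq(-0.2, 0.2, by = 1 / fs)) / 0.06)^2)  # ~400 ms bump
      half <- (length(blink_shape) - 1) / 2
      for (bt in blink_t) {
        i0 <- round(bt * fs) - half
        idx <- i0:(i0 + length(blink_shape) - 1)
        keep <- idx >= 1 & idx <= n_samp
        for (ch in mon$frontal) {
          c <- match(ch, mon$labels)
          data[c, idx[keep]] <- data[c, idx[keep]] +
            effect$blink_amplitude * blink_shape[keep]
        }
      }
    }
  }

  # mains line noise, common phase across channels
  if (effect$line_noise_amplitude > 0) {
    line <- effect$line_noise_amplitude * sin(2 * pi * 60 * tvec + stats::runif(1, 0, 2 * pi))
    data <- sweep(data, 2, line, `+`)
  }

  events <- rbind(
    data.frame(onset_sample = seq_tab$onset_sample, duration = train_n,
               code = seq_tab$code),
    rest_events
  )
  events <- events[order(events$onset_sample), ]
  rownames(events) <- NULL
  eeg_recording(data = data, fs = fs, channel_labels = mon$labels,
                events = events,
                meta = list(dose = dose, rng_seed = rng_seed, rates = rates))
}
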
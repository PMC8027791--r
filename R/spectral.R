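#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every retained trial and channel with complex Morlet wavelets
#' `g(t) * exp(i 2 pi f t)`, `g` Gaussian with `sd = n_cycles / (2 pi f)`,
#' truncated at 3.5 sd. Kernels are amplitude-normalized so that a pure
#' sinusoid of amplitude `A` microvolts at a matching frequency yields
#' coefficients of magnitude `A`; `|coeff|^2` is therefore proportional to
#' power in microvolts squared. Edges are zero-padded, so coefficients
#' within half a kernel of the epoch edges are attenuated — keep scoring
#' and baseline windows away from the edges.
#'
#' @param epochs An `eeg_epochs` (rejected trials are dropped first).
#' @param freqs Analysis frequencies, Hz, strictly increasing, below
#'   Nyquist.
#' @param n_cycles Wavelet width in cycles (scalar, applied at every
#'   frequency).
#' @param channels Channel labels to decompose (default: all).
#'
#' @return An object of class `eeg_tfr`: complex `coefficients` array
#'   (trials x channels x freqs x times), `freqs`, `times` (seconds,
#'   epoch grid), `n_cycles`, `fs`, `condition`, `channel_labels`.
#' @export
morlet_tfr <- function(epochs, freqs, n_cycles = 7, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epochs <- retained(epochs)
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stop("freqs must be below Nyquist (", fs / 2, " Hz)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  ch_idx <- if (is.null(channels)) seq_along(epochs$channel_labels)
            else match(channels, epochs$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channel(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  n_trial <- dim(epochs$data)[1]
  n_time <- dim(epochs$data)[3]
  if (n_trial < 1) stop("no retained trials")

  kernels <- lapply(freqs, function(f) {
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * fs)
    if (2 * half + 1 > n_time) {
      stop("wavelet at ", f, " Hz (", round((2 * half + 1) / fs, 3),
           " s) is longer than the epoch (", round(n_time / fs, 3), " s)")
    }
    tt <- seq(-half, half) / fs
    g <- exp(-tt^2 / (2 * sd_t^2))
    k <- g * exp(1i * 2 * pi * f * tt)
    k * (2 / sum(g))                       # sinusoid amplitude A -> |coeff| = A
  })

  nfft <- stats::nextn(n_time + max(lengths(kernels)) - 1, 2)
  K <- lapply(kernels, function(k) stats::fft(c(k, rep(0, nfft - length(k)))))
  halves <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))

  out <- array(complex(1), dim = c(n_trial, length(ch_idx), length(freqs), n_time))
  for (tr in seq_len(n_trial)) {
    for (ci in seq_along(ch_idx)) {
      x <- epochs$data[tr, ch_idx[ci], ]
      X <- stats::fft(c(x, rep(0, nfft - n_time)))
      for (fi in seq_along(freqs)) {
        y <- stats::fft(X * K[[fi]], inverse = TRUE) / nfft
        out[tr, ci, fi, ] <- y[halves[fi] + seq_len(n_time)]
      }
    }
  }
  structure(list(coefficients = out, freqs = freqs,
                 times = epochs$tmin + (seq_len(n_time) - 1) / fs,
                 n_cycles = n_cycles, fs = fs, condition = epochs$condition,
                 channel_labels = epochs$channel_labels[ch_idx]),
            class = "eeg_tfr")
}

#' Inter-trial phase coherence
#'
#' `ITPC(c, f, t) = | mean_n coeff_n / |coeff_n| |` over retained trials:
#' the magnitude of the mean unit phase vector, 1 for perfect phase locking
#' and near the Rayleigh null `sqrt(pi)/(2 sqrt(N))` for N uniform-random
#' phases. Zero-magnitude coefficients are excluded from the mean at that
#' point (their phase is undefined).
#'
#' @param tfr An `eeg_tfr` with at least 2 trials.
#' @return Numeric array channels x freqs x times in [0, 1].
#' @export
itpc <- function(tfr) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  co <- tfr$coefficients
  if (dim(co)[1] < 2) stop("ITPC needs at least 2 retained trials")
  mag <- Mod(co)
  unit <- co / mag
  unit[mag == 0] <- NA_complex_
  n_excluded <- sum(mag == 0)
  if (n_excluded > 0) {
    message("itpc: excluded ", n_excluded, " zero-magnitude coefficient(s)")
  }
  m <- apply(unit, c(2, 3, 4), function(z) abs(mean(z, na.rm = TRUE)))
  m
}

#' Baseline-corrected evoked power
#'
#' Trial-averaged wavelet power corrected against the pre-stimulus mean,
#' per channel and frequency. `mode = "relchange"` returns
#' `(P - B)/B`; `mode = "db"` returns `10 log10(P/B)`.
#'
#' @param tfr An `eeg_tfr`.
#' @param baseline_window `c(t0, t1)` seconds, strictly pre-stimulus and
#'   inside the epoch; must be at least `n_cycles / (2 min(freqs))` long
#'   (half a wavelet span).
#' @param mode `"relchange"` or `"db"`.
#' @return Numeric array channels x freqs x times.
#' @export
evoked_power <- function(tfr, baseline_window = c(-0.4, -0.1),
                         mode = c("relchange", "db")) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  mode <- match.arg(mode)
  b0 <- baseline_window[1]; b1 <- baseline_window[2]
  if (!(b1 <= 0 && b0 < b1)) stop("baseline window must precede stimulus onset")
  if (b0 < min(tfr$times)) stop("baseline window outside the epoch")
  min_len <- tfr$n_cycles / (2 * min(tfr$freqs))
  if (b1 - b0 < min_len) {
    stop("baseline window (", b1 - b0, " s) shorter than half a wavelet at ",
         min(tfr$freqs), " Hz (", signif(min_len, 3), " s)")
  }
  pow <- apply(Mod(tfr$coefficients)^2, c(2, 3, 4), mean)   # ch x freq x time
  bidx <- which(tfr$times >= b0 & tfr$times <= b1)
  base <- apply(pow[, , bidx, drop = FALSE], c(1, 2), mean) # ch x freq
  rel <- sweep(pow, c(1, 2), base, `/`)
  if (mode == "relchange") rel - 1 else 10 * log10(rel)
}

#' Scalar ASSR score
#'
#' Collapses a time-frequency measure to the conventional steady-state
#' scalar: the mean over an ROI channel set, a band around the stimulation
#' rate, and a post-onset scoring window. Produces either the
#' inter-trial phase coherence or baseline-corrected evoked power.
#'
#' @param epochs An `eeg_epochs` for one stimulation-rate condition.
#' @param measure `"itpc"` or `"power"`.
#' @param roi ROI channel labels (default fronto-central Fz/FCz/Cz).
#' @param band_halfwidth Half-width of the scoring band around the
#'   stimulation rate, Hz.
#' @param window Scoring window, seconds post-onset.
#' @param n_cycles Wavelet width in cycles.
#' @param baseline_window Pre-stimulus window for power correction.
#' @param mode Power correction mode, see [evoked_power()].
#' @return A list of class `assr_score`: `value` (scalar, NA with a
#'   `reason` if fewer than 2 trials survive), `condition`, `measure`,
#'   `roi`, `band`, `window`, `n_trials`.
#' @export
assr_score <- function(epochs, measure = c("itpc", "power"),
                       roi = c("Fz", "FCz", "Cz"), band_halfwidth = 2,
                       window = c(0.1, 0.5), n_cycles = 7,
                       baseline_window = c(-0.4, -0.1),
                       mode = "relchange") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  measure <- match.arg(measure)
  if (length(roi) == 0) stop("roi must be non-empty")
  rate <- epochs$condition
  band <- c(rate - band_halfwidth, rate + band_halfwidth)
  n_keep <- sum(is.na(epochs$rejected))
  if (n_keep < 2) {
    warning("assr_score: only ", n_keep, " retained trial(s) for ", rate,
            " Hz; returning NA")
    return(structure(list(value = NA_real_, reason = "insufficient_trials",
                          condition = rate, measure = measure, roi = roi,
                          band = band, window = window, n_trials = n_keep),
                     class = "assr_score"))
  }
  freqs <- seq(band[1], band[2])
  tfr <- morlet_tfr(epochs, freqs = freqs, n_cycles = n_cycles, channels = roi)
  tidx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  val <- if (measure == "itpc") {
    m <- itpc(tfr)
    mean(m[, , tidx])
  } else {
    p <- evoked_power(tfr, baseline_window = baseline_window, mode = mode)
    mean(p[, , tidx])
  }
  structure(list(value = val, reason = NULL, condition = rate,
                 measure = measure, roi = roi, band = band, window = window,
                 n_trials = n_keep),
            class = "assr_score")
}

#' @export
print.assr_score <- function(x, ...) {
  cat(sprintf("<assr_score> %d Hz %s = %s (%d trials, ROI %s)\n",
              x$condition, x$measure,
              if (is.na(x$value)) paste0("NA [", x$reason, "]") else signif(x$value, 4),
              x$n_trials, paste(x$roi, collapse = "/")))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: each segment is split into Hamming-tapered
#' windows of `window_s` seconds with fractional `overlap`, and one-sided
#' periodograms (density scaling, microvolts squared per Hz) are averaged
#' across windows and segments. Frequency resolution is `1 / window_s`.
#'
#' @param segments A channels x samples matrix, or a list of such matrices
#'   (e.g. one per resting segment). All segments must be at least
#'   `window_s` long.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds.
#' @param overlap Fractional overlap in [0, 1).
#' @param channel_labels Optional labels for the rows.
#' @return An object of class `eeg_psd`: `freqs` (Hz), `power`
#'   (channels x freqs), `n_windows`, `window_s`, `overlap`,
#'   `taper = "hamming"`, `channel_labels`.
#' @export
welch_psd <- function(segments, fs, window_s = 2, overlap = 0.5,
                      channel_labels = NULL) {
  if (is.matrix(segments)) segments <- list(segments)
  if (length(segments) == 0) stop("no usable segments")
  nwin <- round(window_s * fs)
  if (any(vapply(segments, ncol, integer(1)) < nwin)) {
    stop("every segment must be at least window_s = ", window_s, " s long")
  }
  n_ch <- nrow(segments[[1]])
  w <- signal::hamming(nwin)
  U <- sum(w^2)
  step <- max(1L, round(nwin * (1 - overlap)))
  acc <- matrix(0, n_ch, nwin %/% 2 + 1)
  n_seg_win <- 0L
  for (seg in segments) {
    starts <- seq(1L, ncol(seg) - nwin + 1L, by = step)
    for (s0 in starts) {
      idx <- s0 + seq_len(nwin) - 1L
      for (c in seq_len(n_ch)) {
        x <- seg[c, idx] * w
        P <- Mod(stats::fft(x))^2 / (fs * U)
        half <- P[seq_len(nwin %/% 2 + 1)]
        half[2:(length(half) - if (nwin %% 2 == 0) 1 else 0)] <-
          2 * half[2:(length(half) - if (nwin %% 2 == 0) 1 else 0)]
        acc[c, ] <- acc[c, ] + half
      }
      n_seg_win <- n_seg_win + 1L
    }
  }
  structure(list(freqs = seq(0, nwin %/% 2) * fs / nwin,
                 power = acc / n_seg_win, n_windows = n_seg_win,
                 window_s = window_s, overlap = overlap, taper = "hamming",
                 channel_labels = channel_labels),
            class = "eeg_psd")
}

#' Band-integrated resting power in decibels
#'
#' `10 log10` of the band-integrated power (trapezoid-free Riemann sum,
#' `sum(power) * df`), averaged over channels, with declared notch bands
#' excluded from the integration.
#'
#' @param psd An `eeg_psd`.
#' @param band `c(low, high)` Hz.
#' @param exclude List of `c(low, high)` bands excluded from integration
#'   (default the 58-62 Hz mains notch).
#' @param channels Channel labels to average (default all; requires
#'   `channel_labels` on the psd when given).
#' @return Scalar dB.
#' @export
gamma_power_db <- function(psd, band = c(30, 50),
                           exclude = list(c(58, 62)), channels = NULL) {
  stopifnot(inherits(psd, "eeg_psd"))
  keep_f <- psd$freqs >= band[1] & psd$freqs <= band[2]
  for (ex in exclude) keep_f <- keep_f & !(psd$freqs >= ex[1] & psd$freqs <= ex[2])
  if (!any(keep_f)) stop("no frequency bins in band [", band[1], ", ", band[2], "] Hz")
  rows <- if (is.null(channels)) seq_len(nrow(psd$power))
          else match(channels, psd$channel_labels)
  if (anyNA(rows)) stop("unknown channel(s) in gamma_power_db")
  df <- psd$freqs[2] - psd$freqs[1]
  bp <- mean(rowSums(psd$power[rows, keep_f, drop = FALSE]) * df)
  if (bp <= 0) stop("zero band power: cannot take 10*log10")
  10 * log10(bp)
}

#' Aperiodic 1/f spectral slope
#'
#' Ordinary least-squares slope of `log10(power)` against `log10(f)` over
#' `fit_range`, with oscillatory bands (alpha/theta peaks by default)
#' excluded from the fit. The channel-averaged spectrum is fitted. The
#' slope of `1/f^chi` noise estimates `-chi`.
#'
#' @param psd An `eeg_psd`.
#' @param fit_range `c(low, high)` Hz.
#' @param excluded_bands List of `c(low, high)` bands removed from the fit.
#' @param channels Channel labels to average (default all).
#' @return A list of class `aperiodic_fit`: `slope`, `se`, `intercept`,
#'   `n_points`, `fit_range`, `excluded_bands`.
#' @export
aperiodic_slope <- function(psd, fit_range = c(3, 40),
                            excluded_bands = list(c(6, 14)), channels = NULL) {
  stopifnot(inherits(psd, "eeg_psd"))
  keep <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2] & psd$freqs > 0
  for (ex in excluded_bands) keep <- keep & !(psd$freqs >= ex[1] & psd$freqs <= ex[2])
  if (sum(keep) < 10) {
    stop("aperiodic fit needs >= 10 frequency points, got ", sum(keep))
  }
  rows <- if (is.null(channels)) seq_len(nrow(psd$power))
          else match(channels, psd$channel_labels)
  spec <- colMeans(psd$power[rows, , drop = FALSE])
  fit <- stats::lm(log10(spec[keep]) ~ log10(psd$freqs[keep]))
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
                 intercept = unname(sm[1, 1]), n_points = sum(keep),
                 fit_range = fit_range, excluded_bands = excluded_bands),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> slope = %.3f (SE %.3f), %d points in %g-%g Hz\n",
              x$slope, x$se, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Resting-state scores from a recording
#'
#' Extracts the two resting outcome measures from a recording's
#' eyes-closed/eyes-open segments: gamma band power in dB and the aperiodic
#' 1/f slope. Eyes-closed and eyes-open segments are Welch-averaged
#' separately and the two spectra combined with equal weight.
#'
#' @param recording An `eeg_recording` with EC/EO events.
#' @param gamma_band Gamma integration band, Hz.
#' @param notch Excluded mains band, Hz.
#' @param slope_range Slope fit range, Hz.
#' @param slope_exclude Bands excluded from the slope fit.
#' @param window_s,overlap Welch parameters.
#' @return List with `gamma_db`, `slope` (an `aperiodic_fit`), `psd`.
#' @export
resting_scores <- function(recording, gamma_band = c(30, 50),
                           notch = c(58, 62), slope_range = c(3, 40),
                           slope_exclude = list(c(6, 14)),
                           window_s = 2, overlap = 0.5) {
  segs <- resting_segments(recording)
  psd_ec <- welch_psd(segs$EC, recording$fs, window_s, overlap,
                      recording$channel_labels)
  psd_eo <- welch_psd(segs$EO, recording$fs, window_s, overlap,
                      recording$channel_labels)
  psd <- psd_ec
  psd$power <- (psd_ec$power + psd_eo$power) / 2
  psd$n_windows <- psd_ec$n_windows + psd_eo$n_windows
  list(gamma_db = gamma_power_db(psd, gamma_band, list(notch)),
       slope = aperiodic_slope(psd, slope_range, slope_exclude),
       psd = psd)
}
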
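# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately naive (loops, direct definitions) and never call
# the implementation paths they check.

# Log-log periodogram slope of a signal generator, averaged over `n_real`
# realizations: the brute-force oracle for spectral exponents.
periodogram_slope <- function(gen, n_real, n_samples, fs, fmin = 2, fmax = 80) {
  acc <- NULL
  for (r in seq_len(n_real)) {
    x <- gen(r)
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n
    f <- seq(0, n - 1) * fs / n
    keep <- f >= fmin & f <= fmax & seq_along(f) <= n / 2
    if (is.null(acc)) acc <- numeric(sum(keep))
    acc <- acc + p[keep]
  }
  f <- seq(0, n_samples - 1) * fs / n_samples
  keep <- f >= fmin & f <= fmax & seq_along(f) <= n_samples / 2
  unname(stats::coef(stats::lm(log10(acc / n_real) ~ log10(f[keep])))[2])
}

# Direct single-frequency complex demodulation: Gaussian-windowed correlation
# with exp(-i 2 pi f t), computed as an explicit loop. Same normalization
# convention as the wavelet path (sinusoid amplitude A -> |coeff| = A).
demod_oracle <- function(x, fs, f, n_cycles = 7) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * fs)
  n <- length(x)
  out <- complex(real = rep(NA_real_, n))
  for (t0 in seq_len(n)) {
    lo <- t0 - half; hi <- t0 + half
    if (lo < 1 || hi > n) next
    tau <- (lo:hi - t0) / fs
    g <- exp(-tau^2 / (2 * sd_t^2))
    out[t0] <- sum(x[lo:hi] * g * exp(-1i * 2 * pi * f * tau)) * 2 / sum(g)
  }
  out
}

# Construct an eeg_epochs object directly from a trials x samples matrix
# (single channel) without going through a recording.
epochs_from_matrix <- function(m, fs, tmin = -0.5, condition = 40,
                               label = "Cz") {
  arr <- array(0, dim = c(nrow(m), 1, ncol(m)))
  arr[, 1, ] <- m
  structure(list(data = arr, tmin = tmin, fs = fs, condition = condition,
                 channel_labels = label,
                 rejected = rep(NA_character_, nrow(m))),
            class = "eeg_epochs")
}

# Construct an eeg_tfr directly from a trials x times complex matrix at one
# channel and one frequency.
tfr_from_coeffs <- function(co, freq = 40, fs = 500, tmin = 0, n_cycles = 7) {
  arr <- array(complex(1), dim = c(nrow(co), 1, 1, ncol(co)))
  arr[, 1, 1, ] <- co
  structure(list(coefficients = arr, freqs = freq,
                 times = tmin + (seq_len(ncol(co)) - 1) / fs,
                 n_cycles = n_cycles, fs = fs, condition = freq,
                 channel_labels = "Cz"),
            class = "eeg_tfr")
}

# Small recording for I/O and preprocessing tests.
tiny_recording <- function(seed = 1, n_standard = 10, fs = 500,
                           rest_segment_s = 10) {
  simulate_recording("placebo",
                     spec = click_train_spec(n_standard = n_standard,
                                             n_oddball = 2),
                     fs = fs, rest_segment_s = rest_segment_s,
                     n_rest_cycles = 1, rng_seed = seed)
}

# Feature-level null and effect simulators with explicit parameters, used
# by the statistics operating-characteristic tests.
sim_null_table <- function(seed) {
  simulate_feature_study(n_subjects = 10,
                         effects = c(placebo = 0, low = 0, high = 0),
                         rng_seed = seed)
}
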
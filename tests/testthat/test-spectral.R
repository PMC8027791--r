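test_that("Morlet coefficients behave as an eigen-analysis of sinusoids", {
  fs <- 500
  t <- seq(-0.5, 0.999, by = 1 / fs)
  a <- 1.7
  x <- a * sin(2 * pi * 40 * t + 0.3)
  ep <- epochs_from_matrix(matrix(rep(x, 3), 3, byrow = TRUE), fs = fs)
  tfr <- morlet_tfr(ep, freqs = 35:45)
  pow <- apply(Mod(tfr$coefficients)^2, 3, mean)       # mean power per freq
  expect_equal(tfr$freqs[which.max(pow)], 40)
  # amplitude normalization: |coeff| ~ a at the matching frequency, mid-epoch
  mid <- which.min(abs(tfr$times - 0.25))
  expect_equal(Mod(tfr$coefficients[1, 1, 6, mid]), a, tolerance = 0.01)

  # quadratic scaling: doubling amplitude quadruples power
  ep2 <- epochs_from_matrix(matrix(2 * x, 1), fs = fs)
  tfr2 <- morlet_tfr(ep2, freqs = 35:45)
  expect_equal(Mod(tfr2$coefficients[1, 1, 6, mid])^2,
               4 * Mod(tfr$coefficients[1, 1, 6, mid])^2, tolerance = 1e-6)

  expect_error(morlet_tfr(ep, freqs = c(2, 10)), "longer than the epoch")
  expect_error(morlet_tfr(ep, freqs = c(40, 400)), "Nyquist")
})

test_that("Morlet coefficients agree with a direct complex-demodulation oracle within 2%", {
  fs <- 500
  set.seed(13)
  t <- seq(-0.5, 0.999, by = 1 / fs)
  x <- 2 * sin(2 * pi * 40 * t + 1.1) + colored_noise(length(t), fs, 1)
  ep <- epochs_from_matrix(matrix(x, 1), fs = fs)
  tfr <- morlet_tfr(ep, freqs = 39:41)
  oracle <- demod_oracle(x, fs, 40)
  valid <- which(!is.na(Re(oracle)))
  mid <- valid[valid > 200 & valid < 550]
  rel_err <- Mod(tfr$coefficients[1, 1, 2, mid] - oracle[mid]) / Mod(oracle[mid])
  expect_lt(max(rel_err), 0.02)
})

test_that("ITPC is exact in the locking limits and bounded in [0, 1]", {
  n_t <- 100
  phases <- rep(0.4, 50)
  co <- outer(exp(1i * phases), rep(1 + 0i, n_t)) * 3   # identical phase, any magnitude
  expect_equal(max(abs(itpc(tfr_from_coeffs(co)) - 1)), 0, tolerance = 1e-12)

  co2 <- rbind(exp(1i * rep(0.9, n_t)), exp(1i * rep(0.9 + pi, n_t)))
  expect_equal(max(itpc(tfr_from_coeffs(co2))), 0, tolerance = 1e-12)

  set.seed(3)
  co3 <- matrix(exp(1i * runif(40 * n_t, -pi, pi)), 40)
  v <- itpc(tfr_from_coeffs(co3))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(itpc(tfr_from_coeffs(co3[1, , drop = FALSE])), "2 retained")
})

test_that("ITPC at N=110 uniform phases matches the Monte-Carlo Rayleigh-null oracle", {
  n_trials <- 110
  # oracle: direct mean resultant length of uniform unit vectors
  set.seed(41)
  oracle <- replicate(1000, abs(mean(exp(1i * runif(n_trials, -pi, pi)))))
  # implementation: itpc over synthetic uniform-phase coefficient arrays
  set.seed(42)
  impl <- replicate(200, {
    co <- matrix(exp(1i * runif(n_trials, -pi, pi)), n_trials, 1)
    itpc(tfr_from_coeffs(co))[1, 1, 1]
  })
  se <- sd(impl) / sqrt(length(impl))
  expect_lt(abs(mean(impl) - mean(oracle)), 3 * se)
  # and both sit near the analytic sqrt(pi)/(2 sqrt(N))
  expect_equal(mean(oracle), sqrt(pi) / (2 * sqrt(n_trials)), tolerance = 0.05)
})

test_that("evoked power is zero for stationary signals and follows power ratios", {
  fs <- 500
  t <- seq(-0.5, 0.999, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)                       # same in baseline and stimulation
  ep <- epochs_from_matrix(matrix(x, 1), fs = fs)
  tfr <- morlet_tfr(ep, freqs = 38:42)
  rel <- evoked_power(tfr, baseline_window = c(-0.4, -0.1), mode = "relchange")
  tidx <- tfr$times >= 0.1 & tfr$times <= 0.5
  expect_equal(mean(rel[1, 3, tidx]), 0, tolerance = 0.01)

  # stimulation amplitude sqrt(2) x baseline -> power ratio 2 -> relchange 1 / +3.01 dB
  amp <- ifelse(t >= 0, sqrt(2), 1)
  ep2 <- epochs_from_matrix(matrix(amp * sin(2 * pi * 40 * t), 1), fs = fs)
  tfr2 <- morlet_tfr(ep2, freqs = 38:42)
  rel2 <- evoked_power(tfr2, mode = "relchange")
  db2 <- evoked_power(tfr2, mode = "db")
  expect_equal(mean(rel2[1, 3, tidx]), 1, tolerance = 0.03)
  expect_equal(mean(db2[1, 3, tidx]), 10 * log10(2), tolerance = 0.1)

  expect_error(evoked_power(tfr, baseline_window = c(-0.45, -0.41)), "shorter")
  expect_error(evoked_power(tfr, baseline_window = c(0.1, 0.4)), "precede")
})

test_that("ASSR scores are invariant to ROI channel order and flag empty trial sets", {
  rec <- tiny_recording(seed = 17)
  rec <- average_reference(bandpass(rec, 1, 80))
  ep <- epoch_recording(rec, 40)
  s1 <- assr_score(ep, "itpc", roi = c("Fz", "FCz", "Cz"))
  s2 <- assr_score(ep, "itpc", roi = c("Cz", "Fz", "FCz"))
  expect_equal(s1$value, s2$value, tolerance = 1e-12)

  ep_bad <- ep
  ep_bad$rejected[] <- "p2p"
  expect_warning(s3 <- assr_score(ep_bad, "itpc"), "retained")
  expect_true(is.na(s3$value))
  expect_equal(s3$reason, "insufficient_trials")
})

test_that("Welch spectra conserve variance and resolve sinusoid power (Parseval oracle)", {
  fs <- 500
  set.seed(19)
  x <- rnorm(fs * 60)                          # unit-variance white noise
  psd <- welch_psd(matrix(x, 1), fs, window_s = 2, overlap = 0.5)
  df <- psd$freqs[2] - psd$freqs[1]
  expect_equal(sum(psd$power[1, ]) * df, 1, tolerance = 0.02)

  a <- 3
  y <- a * sin(2 * pi * 40 * seq(0, 60, by = 1 / fs))
  psd2 <- welch_psd(matrix(y, 1), fs, window_s = 2, overlap = 0.5)
  band <- psd2$freqs >= 35 & psd2$freqs <= 45
  expect_equal(sum(psd2$power[1, band]) * df, a^2 / 2, tolerance = 0.02 * a^2 / 2)

  # doubling the window halves the bin width
  psd4 <- welch_psd(matrix(x, 1), fs, window_s = 4)
  expect_equal(psd4$freqs[2] - psd4$freqs[1], df / 2)
  expect_error(welch_psd(matrix(x[1:100], 1), fs, window_s = 2), "window_s")
})

test_that("band power in dB follows the decade rule", {
  fake_psd <- structure(list(freqs = seq(0, 100, by = 0.5),
                             power = matrix(0, 1, 201),
                             channel_labels = "Cz"), class = "eeg_psd")
  # flat density such that band-integrated 30-50 Hz power = 1 uV^2
  keep <- fake_psd$freqs >= 30 & fake_psd$freqs <= 50
  fake_psd$power[1, keep] <- 1 / (sum(keep) * 0.5)
  expect_equal(gamma_power_db(fake_psd, c(30, 50), exclude = list()), 0,
               tolerance = 1e-12)
  fake_psd$power <- fake_psd$power * 10
  expect_equal(gamma_power_db(fake_psd, c(30, 50), exclude = list()), 10,
               tolerance = 1e-12)
  fake_psd$power[] <- 0
  expect_error(gamma_power_db(fake_psd, c(30, 50)), "zero band power")
})

test_that("the aperiodic slope estimator recovers generating exponents within 0.1", {
  fs <- 500
  for (chi in c(0, 1)) {
    set.seed(50 + 10 * chi)
    slopes <- replicate(30, {
      x <- colored_noise(fs * 8, fs, chi)
      psd <- welch_psd(matrix(x, 1), fs, window_s = 2)
      aperiodic_slope(psd, fit_range = c(3, 40), excluded_bands = list())$slope
    })
    expect_equal(mean(slopes), -chi, tolerance = 0.1)
  }
})

test_that("excluded oscillatory bands do not bias the aperiodic slope", {
  fs <- 500
  set.seed(77)
  t <- seq(0, 60, by = 1 / fs)
  base <- colored_noise(length(t), fs, 1)
  with_alpha <- base + 5 * sin(2 * pi * 10 * t)
  s0 <- aperiodic_slope(welch_psd(matrix(base, 1), fs),
                        excluded_bands = list(c(6, 14)))$slope
  s1 <- aperiodic_slope(welch_psd(matrix(with_alpha, 1), fs),
                        excluded_bands = list(c(6, 14)))$slope
  expect_equal(s1, s0, tolerance = 0.05)
  # without the exclusion the alpha peak drags the fit
  s2 <- aperiodic_slope(welch_psd(matrix(with_alpha, 1), fs),
                        excluded_bands = list())$slope
  expect_gt(abs(s2 - s0), abs(s1 - s0))
  expect_error(aperiodic_slope(welch_psd(matrix(base, 1), fs),
                               fit_range = c(3, 5)), "10 frequency points")
})

test_that("high-dose simulations exceed placebo in evoked gamma power and resting gamma dB", {
  one <- function(dose, seed) {
    rec <- simulate_recording(dose,
                              spec = click_train_spec(n_standard = 110, n_oddball = 0),
                              fs = 250, rest_segment_s = 20, n_rest_cycles = 1,
                              rng_seed = seed)
    rec <- average_reference(bandpass(rec, 1, 80))
    ep <- reject_peak_to_peak(epoch_recording(rec, 40), 150)
    c(pow = assr_score(ep, "power")$value,
      g_db = resting_scores(rec)$gamma_db)
  }
  seeds <- 1:20
  res_p <- sapply(seeds, function(s) one("placebo", 1000 + s))
  res_h <- sapply(seeds, function(s) one("high", 2000 + s))
  # evoked 40 Hz power higher under high dose for every seed
  expect_true(all(res_h["pow", ] > res_p["pow", ]))
  # resting gamma dB higher on average
  expect_gt(mean(res_h["g_db", ]), mean(res_p["g_db", ]))
})
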
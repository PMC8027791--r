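test_that("band-pass keeps in-band sinusoids and removes slow drift (filter-response oracle)", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(f0) eeg_recording(matrix(sin(2 * pi * f0 * t), 1), fs, "Cz")
  mid <- function(x) x[round(length(x) * 0.25):round(length(x) * 0.75)]

  y40 <- bandpass(mk(40), 1, 80)$data[1, ]
  att40 <- 1 - max(abs(mid(y40)))
  expect_lt(att40, 0.01)                      # < 1% amplitude loss at 40 Hz

  y01 <- bandpass(mk(0.1), 1, 80)$data[1, ]
  expect_gt(1 - max(abs(mid(y01))), 0.90)     # > 90% attenuation of drift

  expect_error(bandpass(mk(10), 1, 300), "Nyquist|fs/2")
})

test_that("filtering is zero-phase and composes like an LTI system", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  rec <- eeg_recording(matrix(x, 1), fs, "Cz")
  y1 <- bandpass(rec, 1, 80)$data[1, ]
  mid <- round(length(t) * 0.3):round(length(t) * 0.7)
  # zero-phase: filtered signal in phase with the input
  expect_gt(cor(x[mid], y1[mid]), 0.9999)
  # composition: filtering twice ~ squared magnitude response
  y2 <- bandpass(bandpass(rec, 1, 80), 1, 80)$data[1, ]
  a1 <- max(abs(y1[mid])); a2 <- max(abs(y2[mid]))
  expect_equal(a2, a1^2, tolerance = 0.01)
})

test_that("epoching is index-exact and grouped by stimulation rate", {
  fs <- 500
  n <- 20 * fs
  ramp <- matrix(seq_len(n), 1)               # sample index as the signal value
  ev <- data.frame(onset_sample = c(1000, 5000), duration = 250,
                   code = "assr40")
  rec <- eeg_recording(ramp, fs, "Cz", events = ev)
  ep <- epoch_recording(rec, 40, window = c(-0.5, 1.0))
  expect_equal(dim(ep$data), c(2, 1, 750))
  # epoch sample k (1-based) = recording sample onset + round(tmin*fs) + k,
  # 0-based; the ramp encodes 1-based sample index = 0-based + 1
  expect_equal(ep$data[1, 1, 1], 1000 - 250 + 1)
  expect_equal(ep$data[2, 1, 750], 5000 - 250 + 750)
})

test_that("a full block yields one epoch per standard trial and no oddball epochs", {
  rec <- simulate_recording("placebo", spec = click_train_spec(),
                            fs = 500, rest_segment_s = 5, n_rest_cycles = 1,
                            rng_seed = 2, rates = c(40, 30, 20))
  ep <- epoch_recording(rec, 40, window = c(-0.5, 1.0))
  expect_equal(dim(ep$data)[1], 110)
  # oddball codes exist in the events but are never epoched
  expect_gt(sum(grepl("^oddball", rec$events$code)), 0)
  expect_error(epoch_recording(rec, 35), "no events")
})

test_that("trials whose window leaves the recording are flagged, not dropped", {
  rec <- eeg_recording(matrix(0, 1, 1000), 500, "Cz",
                       events = data.frame(onset_sample = c(0, 600),
                                           duration = 250, code = "assr40"))
  ep <- epoch_recording(rec, 40, window = c(-0.5, 1.0))
  expect_equal(ep$rejected, c("out_of_bounds", "out_of_bounds"))
  rec2 <- eeg_recording(matrix(0, 1, 2000), 500, "Cz",
                        events = data.frame(onset_sample = c(0, 400),
                                            duration = 250, code = "assr40"))
  ep2 <- epoch_recording(rec2, 40, window = c(-0.5, 1.0))
  expect_equal(ep2$rejected, c("out_of_bounds", NA))
})

test_that("peak-to-peak rejection flags constructed blinks and is idempotent", {
  m <- matrix(0, 4, 500)
  m[2, ] <- 100 * sin(2 * pi * 1 * seq(0, 0.998, by = 1 / 500))  # 200 uV p2p blink
  ep <- epochs_from_matrix(rbind(m[1, ], m[2, ], m[3, ]), fs = 500)
  ep$data <- array(0, dim = c(3, 1, 500))
  ep$data[2, 1, ] <- m[2, ]
  ep$rejected <- rep(NA_character_, 3)
  out <- reject_peak_to_peak(ep, threshold = 150)
  expect_equal(out$rejected, c(NA, "p2p", NA))
  # idempotent
  out2 <- reject_peak_to_peak(out, threshold = 150)
  expect_equal(out2$rejected, out$rejected)
  # all-zero trials always retained; infinite threshold is the identity
  expect_true(all(is.na(reject_peak_to_peak(out, threshold = Inf)$rejected[c(1, 3)])))
  # everything rejected -> advisory error
  ep_all <- ep; ep_all$data[, 1, ] <- m[2, ][col(matrix(0, 3, 500))]
  ep_all$data <- array(rep(m[2, ], each = 3), dim = c(3, 1, 500))
  expect_error(reject_peak_to_peak(ep_all, threshold = 10), "review")
  expect_error(reject_peak_to_peak(ep, threshold = -5), "positive")
})
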
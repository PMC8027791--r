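test_that("every subject gets all three doses and the rotation rule holds", {
  d <- crossover_design(12, rng_seed = 4)
  tab <- table(d$subject_id, d$dose)
  expect_true(all(tab == 1))
  rot <- list(high = c("high", "placebo", "low"),
              low = c("low", "high", "placebo"),
              placebo = c("placebo", "low", "high"))
  for (s in unique(d$subject_id)) {
    seqd <- as.character(d$dose[d$subject_id == s][order(d$visit[d$subject_id == s])])
    expect_identical(seqd, rot[[seqd[1]]])
  }
})

test_that("simulated recordings carry the designed events and resting layout", {
  rec <- tiny_recording(seed = 9)
  ev <- rec$events
  expect_equal(sum(grepl("^assr", ev$code)), 3 * 10)   # 10 standards x 3 rates
  expect_equal(sum(grepl("^oddball", ev$code)), 2)
  expect_equal(sum(ev$code == "EC"), 1)
  expect_equal(sum(ev$code == "EO"), 1)

  rec2 <- simulate_recording("placebo",
                             spec = click_train_spec(n_standard = 5, n_oddball = 0),
                             fs = 500, rest_segment_s = 60, n_rest_cycles = 2,
                             rng_seed = 1)
  expect_equal(sum(rec2$events$code == "EC"), 2)       # 2 EC + 2 EO segments
  expect_equal(sum(rec2$events$code == "EO"), 2)
  expect_equal(unique(rec2$events$duration[rec2$events$code %in% c("EC", "EO")]),
               60 * 500)
})

test_that("recordings are bit-identical for identical seed and config", {
  a <- tiny_recording(seed = 21)
  b <- tiny_recording(seed = 21)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  c <- tiny_recording(seed = 22)
  expect_false(identical(a$data, c$data))
})

test_that("unknown dose conditions and bad sampling rates are rejected", {
  expect_error(simulate_recording("mid"), "unknown dose")
  expect_error(simulate_recording("placebo", fs = 100), "fs")
})

test_that("near-perfect phase locking without noise drives ITPC to 1", {
  eff <- effect_config(noise_scale = 1e-6,
                       ssr_amplitude = c(placebo = 2, low = 2, high = 2),
                       phase_concentration = c(placebo = 1e6, low = 1e6, high = 1e6),
                       resting_gamma_amplitude = c(placebo = 0, low = 0, high = 0),
                       alpha_amplitude = 0, blink_rate = 0,
                       line_noise_amplitude = 0)
  rec <- simulate_recording("placebo", effect = eff,
                            spec = click_train_spec(n_standard = 20, n_oddball = 0),
                            fs = 500, rest_segment_s = 5, n_rest_cycles = 1,
                            rng_seed = 3)
  ep <- epoch_recording(rec, 40)
  sc <- assr_score(ep, "itpc")
  expect_gt(sc$value, 0.99)
})

test_that("kappa = 0 drives ITPC down to the uniform-phase null level", {
  eff <- effect_config(ssr_amplitude = c(placebo = 2.1, low = 2.1, high = 2.1),
                       phase_concentration = c(placebo = 0, low = 0, high = 0),
                       blink_rate = 0)
  vals <- sapply(1:4, function(s) {
    rec <- simulate_recording("placebo", effect = eff,
                              spec = click_train_spec(n_standard = 55, n_oddball = 0),
                              fs = 500, rest_segment_s = 5, n_rest_cycles = 1,
                              rng_seed = s)
    assr_score(epoch_recording(rec, 40), "itpc")$value
  })
  # Rayleigh null mean resultant for N trials ~ sqrt(pi)/(2 sqrt(N)); with
  # N = 55 that is 0.12. Allow generous Monte-Carlo spread around it.
  expect_lt(abs(mean(vals) - sqrt(pi) / (2 * sqrt(55))), 0.06)
})
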
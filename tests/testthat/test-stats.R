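test_that("build_design enforces the measure-specific timepoint windows", {
  tab <- simulate_feature_study(n_subjects = 6,
                                timepoints = c("h1", "h2", "h3", "h4", "h5"),
                                rng_seed = 2)
  # EEG measure: hour 5 dropped
  expect_message(d_eeg <- build_design(tab, dose_model_spec("assr40_itpc",
                                                            c("h1", "h2", "h3", "h4"))),
                 "dropping")
  expect_setequal(as.character(unique(d_eeg$time)), c("h1", "h2", "h3", "h4"))
  # metabolite-style spec keeps all five hours
  d_met <- build_design(tab, dose_model_spec("assr40_itpc",
                                             c("h1", "h2", "h3", "h4", "h5")))
  expect_equal(nlevels(d_met$time), 5)
  # baseline rows are covariates, never responses
  expect_false("baseline" %in% as.character(d_eeg$time))
  expect_true(all(is.finite(d_eeg$baseline_value)))
  expect_error(build_design(tab, dose_model_spec("nope")), "not present")
  expect_equal(levels(d_eeg$dose)[1], "placebo")
})

test_that("default model windows follow the measure class", {
  expect_equal(default_model_spec("assr40_itpc")$timepoints,
               c("h1", "h2", "h3", "h4"))
  expect_equal(default_model_spec("KYNA")$timepoints,
               c("h1", "h2", "h3", "h4", "h5"))
})

test_that("an injected high-dose-only effect is recovered with the expected contrast pattern", {
  tab <- simulate_feature_study(n_subjects = 10,
                                effects = c(placebo = 0, low = 0, high = 0.02),
                                rng_seed = 7)
  res <- dose_model(tab, "assr40_itpc")
  ct <- res$contrasts
  est_high <- ct$estimate[ct$contrast == "high_vs_placebo"]
  est_low <- ct$estimate[ct$contrast == "low_vs_placebo"]
  expect_gt(est_high, 0)
  expect_lt(ct$p[ct$contrast == "high_vs_placebo"], 0.05)
  expect_lt(abs(est_low), abs(est_high))          # low sits near zero
  expect_equal(res$df_method, "satterthwaite")
  # CI ordered and consistent with the estimate sign
  expect_true(all(ct$ci_lower < ct$ci_upper))
  expect_true(all(res$emmeans$SE > 0))
})

test_that("relabeling placebo and high flips the contrast sign (equivariance)", {
  tab <- simulate_feature_study(n_subjects = 8,
                                effects = c(placebo = 0, low = 0, high = 0.03),
                                rng_seed = 9)
  swapped <- tab
  swapped$dose <- c(placebo = "high", low = "low", high = "placebo")[swapped$dose]
  r1 <- dose_model(tab, "assr40_itpc")
  r2 <- dose_model(swapped, "assr40_itpc")
  e1 <- r1$contrasts$estimate[r1$contrasts$contrast == "high_vs_placebo"]
  e2 <- r2$contrasts$estimate[r2$contrasts$contrast == "high_vs_placebo"]
  expect_equal(e1, -e2, tolerance = 1e-8)
})

test_that("contrast estimates are invariant to row order", {
  tab <- simulate_feature_study(n_subjects = 8, rng_seed = 10)
  spec <- default_model_spec("assr40_itpc")
  d <- build_design(tab, spec)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  r1 <- fit_dose_model(d, spec); r2 <- fit_dose_model(d2, spec)
  expect_equal(r1$contrasts$estimate, r2$contrasts$estimate, tolerance = 1e-8)
  expect_equal(r1$F_dose, r2$F_dose, tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  tab <- simulate_feature_study(n_subjects = 2, rng_seed = 3)
  spec <- default_model_spec("assr40_itpc")
  expect_error(fit_dose_model(build_design(tab, spec), spec), ">= 3 subjects")
  tab3 <- simulate_feature_study(n_subjects = 5, sd_subject = 0, sd_noise = 0,
                                 sd_response = 0,
                                 effects = c(placebo = 0, low = 0, high = 0),
                                 rng_seed = 4)
  expect_error(fit_dose_model(build_design(tab3, spec), spec), "variance")
})

test_that("the report table mirrors the crossover results layout", {
  tabs <- list(
    simulate_feature_study(n_subjects = 6, rng_seed = 20,
                           effects = c(placebo = 0, low = 0, high = 0.05)),
    simulate_feature_study(n_subjects = 6, measure = "resting_gamma_db",
                           mu = -50, sd_subject = 1, sd_noise = 0.8,
                           rng_seed = 21))
  results <- lapply(tabs, function(tb) dose_model(tb, tb$measure[1]))
  rep_tab <- summarize_results(results)
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(c("mean_placebo", "F_dose", "p_dose", "t_low", "t_high",
                    "ci_high_lower", "ci_high_upper", "significant") %in%
                    names(rep_tab)))
  expect_equal(rep_tab$significant, rep_tab$p_dose < 0.05)

  # JSON + CSV round-trip losslessly
  stem <- file.path(withr::local_tempdir(), "report")
  write_report(rep_tab, stem)
  from_csv <- utils::read.csv(paste0(stem, ".csv"))
  from_json <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)$table
  num <- vapply(rep_tab, is.numeric, logical(1))
  for (cn in names(rep_tab)[num]) {
    expect_equal(from_csv[[cn]], rep_tab[[cn]], tolerance = 1e-12)
    expect_equal(from_json[[cn]], rep_tab[[cn]], tolerance = 1e-12)
  }
  # BH adjustment is available but off by default
  rep_bh <- summarize_results(results, adjust = "BH")
  expect_true("p_dose_adj" %in% names(rep_bh))
})
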
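#' Pipeline configuration
#'
#' A single serializable list of every setting the pipeline uses, from the
#' stimulus design through preprocessing and feature extraction to the
#' statistical models. A run is fully reproduced by its config plus seed.
#'
#' @param seed Master integer seed; all per-recording and per-series seeds
#'   are derived from it deterministically.
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate, Hz.
#' @param stimulus Named list of [click_train_spec()] arguments.
#' @param effect Named list of [effect_config()] arguments.
#' @param pk Named list of [pk_config()] arguments.
#' @param eeg_timepoints Session timepoints at which EEG is recorded
#'   (baseline first).
#' @param pk_timepoints Timepoints at which plasma is sampled.
#' @param rest_segment_s,n_rest_cycles Resting-run layout per recording.
#' @param bandpass `c(low, high)` Hz.
#' @param epoch_window `c(tmin, tmax)` s.
#' @param reject_threshold Peak-to-peak threshold, microvolts.
#' @param roi Scoring ROI channels.
#' @param band_halfwidth Scoring band half-width, Hz.
#' @param score_window Scoring window, s.
#' @param baseline_window Pre-stimulus baseline window, s.
#' @param power_mode `"relchange"` or `"db"` for evoked power.
#' @param gamma_band,notch,slope_range,slope_exclude Resting-spectrum
#'   settings, Hz.
#' @param welch_window_s,welch_overlap Welch settings.
#' @param time_as Time covariate coding for the models.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 10, fs = 500,
                            stimulus = list(), effect = list(), pk = list(),
                            eeg_timepoints = c("baseline", "h1", "h2", "h3", "h4", "h5"),
                            pk_timepoints = c("baseline", "h1", "h2", "h3", "h4", "h5"),
                            rest_segment_s = 60, n_rest_cycles = 2,
                            bandpass = c(1, 80), epoch_window = c(-0.5, 1.0),
                            reject_threshold = 150,
                            roi = c("Fz", "FCz", "Cz"), band_halfwidth = 2,
                            score_window = c(0.1, 0.5),
                            baseline_window = c(-0.4, -0.1),
                            power_mode = "relchange",
                            gamma_band = c(30, 50), notch = c(58, 62),
                            slope_range = c(3, 40),
                            slope_exclude = list(c(6, 14)),
                            welch_window_s = 2, welch_overlap = 0.5,
                            time_as = "categorical") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline config (YAML or JSON)
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param config A [pipeline_config()] (for writing).
#' @return For `read_config`, a `pipeline_config`; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$slope_exclude <- lapply(seq_len(NROW(raw$slope_exclude)), function(i)
    as.numeric(if (is.matrix(raw$slope_exclude)) raw$slope_exclude[i, ]
               else raw$slope_exclude[[i]]))
  cfg <- do.call(pipeline_config, raw)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# deterministic per-item seed stream derived from the master seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647L + 1)
}

build_effect <- function(cfg) do.call(effect_config, cfg$effect)
build_spec <- function(cfg) do.call(click_train_spec, cfg$stimulus)
build_pk <- function(cfg, scale, baseline) {
  args <- cfg$pk
  args$scale <- scale; args$baseline <- baseline
  do.call(pk_config, args)
}

tp_hours <- function(tp) {
  out <- numeric(length(tp))
  h <- tp != "baseline"
  out[h] <- as.numeric(sub("^h", "", tp[h]))
  out
}

#' Simulate a full crossover dataset to disk
#'
#' Generates `n_subjects` x 3 sessions, each with one EEG recording per
#' EEG timepoint (three ASSR blocks at 40/30/20 Hz plus the resting run)
#' written as EDF + events TSV, plasma metabolite series for the full
#' analyte panel written as one CSV, the session design CSV, and a
#' manifest JSON listing every file with its MD5 checksum. Identical
#' config + seed reproduces the dataset bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty existing directory.
#' @return The manifest (invisibly), as a list.
#' @export
simulate_study <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- build_spec(config)
  effect <- build_effect(config)
  design <- crossover_design(config$n_subjects,
                             rng_seed = derive_seed(config$seed, 0))
  utils::write.csv(as.data.frame(design), file.path(out_dir, "design.csv"),
                   row.names = FALSE)
  files <- "design.csv"

  idx <- 0L
  for (i in seq_len(nrow(design))) {
    for (tp in config$eeg_timepoints) {
      idx <- idx + 1L
      rec <- simulate_recording(
        dose = if (tp == "baseline") "placebo" else as.character(design$dose[i]),
        effect = effect, spec = spec, fs = config$fs,
        rest_segment_s = config$rest_segment_s,
        n_rest_cycles = config$n_rest_cycles,
        rng_seed = derive_seed(config$seed, idx))
      fn <- sprintf("%s_visit%d_%s.edf", design$subject_id[i], design$visit[i], tp)
      write_edf(rec, file.path(out_dir, fn))
      files <- c(files, fn, sub("\\.edf$", "_events.tsv", fn))
      message(sprintf("simulate: %s (%s, %s)", fn, design$dose[i], tp))
    }
  }

  panel <- analyte_panel()
  met <- NULL
  for (i in seq_len(nrow(design))) {
    for (a in seq_len(nrow(panel))) {
      idx <- idx + 1L
      pk <- build_pk(config, panel$scale[a], panel$baseline[a])
      dose_mg <- if (panel$dose_responsive[a]) design$dose_mg[i] else 0
      series <- simulate_metabolite(panel$analyte[a], dose_mg, pk,
                                    times = tp_hours(config$pk_timepoints),
                                    rng_seed = derive_seed(config$seed, idx))
      series$subject_id <- design$subject_id[i]
      series$dose <- as.character(design$dose[i])
      series$timepoint <- config$pk_timepoints
      met <- rbind(met, as.data.frame(series))
    }
  }
  utils::write.csv(met, file.path(out_dir, "metabolites.csv"), row.names = FALSE)
  files <- c(files, "metabolites.csv")

  manifest <- list(
    package = "gassr", seed = config$seed,
    n_subjects = config$n_subjects,
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  write_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Extract features from one recording
#'
#' Bandpass + average reference, then per stimulation rate: epoching,
#' peak-to-peak rejection and the ITPC / evoked-power scores; plus the
#' resting gamma power (dB) and aperiodic slope.
#'
#' @param recording An `eeg_recording`.
#' @param config A [pipeline_config()].
#' @return Named numeric vector of the 8 EEG measures.
#' @export
extract_features <- function(recording, config = pipeline_config()) {
  rec <- bandpass(recording, config$bandpass[1], config$bandpass[2])
  rec <- average_reference(rec)
  out <- c()
  for (rate in c(40, 30, 20)) {
    ep <- epoch_recording(rec, rate, config$epoch_window)
    ep <- reject_peak_to_peak(ep, config$reject_threshold)
    message(sprintf("  %d Hz: %d/%d trials retained", rate,
                    sum(is.na(ep$rejected)), length(ep$rejected)))
    for (ms in c("power", "itpc")) {
      sc <- assr_score(ep, ms, roi = config$roi,
                       band_halfwidth = config$band_halfwidth,
                       window = config$score_window,
                       baseline_window = config$baseline_window,
                       mode = config$power_mode)
      out[sprintf("assr%d_%s", rate, ms)] <- sc$value
    }
  }
  rest <- resting_scores(rec, gamma_band = config$gamma_band,
                         notch = config$notch,
                         slope_range = config$slope_range,
                         slope_exclude = config$slope_exclude,
                         window_s = config$welch_window_s,
                         overlap = config$welch_overlap)
  out["resting_gamma_db"] <- rest$gamma_db
  out["resting_slope"] <- rest$slope$slope
  out
}

#' Analyze a simulated (or compatible) dataset
#'
#' Verifies the manifest, extracts all EEG measures from every recording,
#' merges the metabolite series, fits the crossover dose model for every
#' measure (EEG measures over hours 1-4, metabolites over hours 1-5), and
#' writes the feature table, the report table (CSV + JSON) and per-dose
#' grand-average summaries used by [report_study()].
#'
#' @param dataset_dir Directory produced by [simulate_study()].
#' @param out_dir Output directory (defaults to `dataset_dir`).
#' @return List with `features` (the [feature_table()]) and `report`
#'   (the [summarize_results()] table).
#' @export
analyze_study <- function(dataset_dir, out_dir = dataset_dir) {
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  fnames <- vapply(manifest$files, `[[`, "", "name")
  missing <- fnames[!file.exists(file.path(dataset_dir, fnames))]
  if (length(missing)) {
    stop("dataset is missing files listed in the manifest: ",
         paste(missing, collapse = ", "))
  }
  config <- read_config(file.path(dataset_dir, "config.json"))
  design <- utils::read.csv(file.path(dataset_dir, "design.csv"),
                            stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- NULL
  for (i in seq_len(nrow(design))) {
    for (tp in config$eeg_timepoints) {
      fn <- sprintf("%s_visit%d_%s.edf", design$subject_id[i], design$visit[i], tp)
      message("analyze: ", fn)
      rec <- read_edf(file.path(dataset_dir, fn))
      feats <- extract_features(rec, config)
      rows <- rbind(rows, data.frame(subject_id = design$subject_id[i],
                                     dose = design$dose[i], timepoint = tp,
                                     measure = names(feats),
                                     value = unname(feats)))
    }
  }
  met <- utils::read.csv(file.path(dataset_dir, "metabolites.csv"),
                         stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(subject_id = met$subject_id, dose = met$dose,
                                 timepoint = met$timepoint,
                                 measure = met$analyte,
                                 value = met$concentration))
  features <- attach_baseline(rows)
  write_feature_table(features, file.path(out_dir, "features.csv"))

  measures <- unique(features$measure)
  results <- lapply(measures, function(m) dose_model(features, m))
  report <- summarize_results(results)
  write_report(report, file.path(out_dir, "report"),
               meta = list(seed = config$seed, n_subjects = config$n_subjects))
  message(sprintf("analyze: %d measures modelled, %d converged",
                  nrow(report), sum(report$converged)))
  invisible(list(features = features, report = report))
}

#' Render summary figures from an analyzed dataset
#'
#' Produces per-measure hourly trajectories relative to the pretreatment
#' baseline (one line per dose condition) and a contrast overview, written
#' as PNG files. Figures regenerate identically from the same inputs.
#'
#' @param out_dir Directory holding `features.csv` and `report.csv`.
#' @param measures Measures to plot (default: all EEG measures present).
#' @return Character vector of files written, invisibly.
#' @export
report_study <- function(out_dir, measures = NULL) {
  features <- read_feature_table(file.path(out_dir, "features.csv"))
  report <- utils::read.csv(file.path(out_dir, "report.csv"))
  if (is.null(measures)) {
    measures <- intersect(unique(features$measure),
                          c("assr40_power", "assr40_itpc", "resting_gamma_db",
                            "resting_slope"))
  }
  written <- character()
  df <- features[features$measure %in% measures & features$timepoint != "baseline", ]
  df$delta <- df$value - df$baseline_value
  df$hour <- as.numeric(sub("^h", "", df$timepoint))
  agg <- stats::aggregate(delta ~ hour + dose + measure, df, mean)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = hour, y = delta,
                                         colour = dose)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Hours post-dose", y = "Change from baseline",
                  colour = "Dose") +
    ggplot2::theme_minimal()
  f1 <- file.path(out_dir, "trajectories.png")
  ggplot2::ggsave(f1, p, width = 8, height = 5, dpi = 120)
  written <- c(written, f1)

  rep_eeg <- report[report$measure %in% measures, ]
  ct <- rbind(
    data.frame(measure = rep_eeg$measure, contrast = "low vs placebo",
               t = rep_eeg$t_low),
    data.frame(measure = rep_eeg$measure, contrast = "high vs placebo",
               t = rep_eeg$t_high))
  p2 <- ggplot2::ggplot(ct, ggplot2::aes(x = measure, y = t,
                                         fill = contrast)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Contrast t statistic", x = NULL) +
    ggplot2::theme_minimal()
  f2 <- file.path(out_dir, "contrasts.png")
  ggplot2::ggsave(f2, p2, width = 7, height = 4, dpi = 120)
  written <- c(written, f2)
  invisible(written)
}

#' Reduced end-to-end demonstration run
#'
#' Simulates, analyzes and reports a desk-scale dataset (4 subjects,
#' 30 standard trials per block, 30 s resting segments, 250 Hz, EEG at
#' baseline plus hours 1-4) in a few minutes on one CPU. Deterministic
#' for a fixed seed.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param force Overwrite an existing non-empty directory.
#' @param quiet Suppress per-file progress messages.
#' @return The analysis result list from [analyze_study()], invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, force = FALSE, quiet = TRUE) {
  cfg <- demo_config(seed)
  run <- function() {
    simulate_study(cfg, out_dir, force = force)
    res <- analyze_study(out_dir)
    report_study(out_dir)
    res
  }
  res <- if (quiet) suppressMessages(run()) else run()
  invisible(res)
}

#' @rdname run_demo
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed, n_subjects = 4, fs = 250,
    stimulus = list(n_standard = 30, n_oddball = 3),
    eeg_timepoints = c("baseline", "h1", "h2", "h3", "h4"),
    rest_segment_s = 30, n_rest_cycles = 2)
}
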
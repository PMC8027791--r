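#' Click-train stimulus specification
#'
#' Parameters of the auditory steady-state stimulus: a train of brief clicks
#' repeated at the stimulation rate. The defaults describe the canonical
#' gamma-band ASSR paradigm: 500 ms trains of 1 ms clicks (1000 Hz carrier,
#' 80 dB) repeated at 20, 30 or 40 Hz, 110 standard trials per block with
#' rare 2000 Hz oddball trains, and a 3 s inter-trial interval.
#'
#' @param rep_rate Click repetition rate in Hz (20, 30 or 40 for the standard
#'   paradigm; any rate giving a whole number of clicks per train is allowed).
#' @param train_duration Train duration in seconds.
#' @param click_duration Single-click duration in seconds.
#' @param carrier Carrier tone frequency of standard clicks, Hz (metadata at
#'   EEG sampling rates; clicks are rendered as rectangular pulses).
#' @param oddball_carrier Carrier of oddball (attention-check) trains, Hz.
#' @param n_standard Standard trials per block.
#' @param n_oddball Oddball trials per session (interleaved across blocks).
#' @param iti Inter-trial interval (train offset to next onset), seconds.
#' @param level_db Sound level metadata in dB; not used in any computation.
#'
#' @return An object of class `click_train_spec`.
#' @examples
#' spec <- click_train_spec(rep_rate = 40)
#' spec$rep_rate * spec$train_duration  # clicks per train
#' @export
click_train_spec <- function(rep_rate = 40, train_duration = 0.5,
                             click_duration = 0.001, carrier = 1000,
                             oddball_carrier = 2000, n_standard = 110,
                             n_oddball = 11, iti = 3.0, level_db = 80) {
  n_clicks <- rep_rate * train_duration
  if (n_clicks <= 0 || abs(n_clicks - round(n_clicks)) > 1e-9) {
    stop("rep_rate * train_duration must be a positive whole number of clicks (got ",
         signif(n_clicks, 6), ")")
  }
  if (click_duration >= 1 / rep_rate) {
    stop("click_duration must be shorter than the click period 1/rep_rate")
  }
  if (n_standard <= 0) stop("n_standard must be positive")
  if (n_oddball < 0) stop("n_oddball must be non-negative")
  if (iti <= 0) stop("iti must be positive")
  structure(list(rep_rate = rep_rate, train_duration = train_duration,
                 click_duration = click_duration, carrier = carrier,
                 oddball_carrier = oddball_carrier, n_standard = n_standard,
                 n_oddball = n_oddball, iti = iti, level_db = level_db),
            class = "click_train_spec")
}

#' @export
print.click_train_spec <- function(x, ...) {
  cat(sprintf("<click_train_spec> %g Hz x %g s (%d clicks of %g ms), ITI %g s\n",
              x$rep_rate, x$train_duration, round(x$rep_rate * x$train_duration),
              x$click_duration * 1e3, x$iti))
  cat(sprintf("  %d standard + %d oddball trials; carriers %g/%g Hz, %g dB\n",
              x$n_standard, x$n_oddball, x$carrier, x$oddball_carrier, x$level_db))
  invisible(x)
}

#' Render one click train
#'
#' Renders the train as a rectangular-pulse waveform sampled at `fs` and
#' returns the click onset times. Onsets are spaced `1/rep_rate` apart
#' starting at t = 0; total duration equals `train_duration`. At EEG
#' simulation rates the carrier is not rendered: an oddball train differs
#' from a standard train only by its event label, which is what
#' `oddball` records.
#'
#' @param spec A [click_train_spec()].
#' @param fs Sampling rate, Hz. Must render at least one sample per click.
#' @param oddball Logical; labels the train as an oddball (waveform identical).
#'
#' @return A list with `waveform` (numeric, `round(train_duration * fs)`
#'   samples, 0/1 pulses), `onsets` (click onset times, seconds), `fs`,
#'   and `oddball`.
#' @examples
#' tr <- make_click_train(click_train_spec(rep_rate = 40), fs = 1000)
#' head(tr$onsets)  # 0.000 0.025 0.050 ...
#' @export
make_click_train <- function(spec, fs, oddball = FALSE) {
  stopifnot(inherits(spec, "click_train_spec"))
  if (fs * spec$click_duration < 1) {
    stop("fs too low: fewer than one sample per ", spec$click_duration * 1e3,
         " ms click (need fs >= ", ceiling(1 / spec$click_duration), " Hz)")
  }
  n_clicks <- round(spec$rep_rate * spec$train_duration)
  onsets <- (seq_len(n_clicks) - 1) / spec$rep_rate
  n_samp <- round(spec$train_duration * fs)
  waveform <- numeric(n_samp)
  click_len <- max(1L, round(spec$click_duration * fs))
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    waveform[i0:min(n_samp, i0 + click_len - 1L)] <- 1
  }
  list(waveform = waveform, onsets = onsets, fs = fs, oddball = oddball)
}

#' Build the trial sequence for ASSR blocks
#'
#' One block of `n_standard` standard trials per repetition rate; the
#' session's `n_oddball` oddball trials are interleaved at random positions
#' across all blocks. Trial onsets are spaced `train_duration + iti` apart
#' within each block.
#'
#' @param spec A [click_train_spec()]; `n_standard`/`n_oddball` are taken
#'   from it.
#' @param rates Repetition rates of the session's blocks, Hz (one block per
#'   rate, in presentation order).
#' @param rng_seed Integer seed controlling the oddball placement.
#'
#' @return A data frame with one row per trial: `block`, `rate`, `trial`
#'   (index within block), `onset` (seconds from block start), `code`
#'   (`"assr<rate>"` or `"oddball<rate>"`), `oddball` (logical).
#' @examples
#' seq40 <- make_block_sequence(click_train_spec(), rates = 40, rng_seed = 1)
#' table(seq40$oddball)
#' @export
make_block_sequence <- function(spec, rates = c(40, 30, 20), rng_seed = 1L) {
  stopifnot(inherits(spec, "click_train_spec"))
  set.seed(as.integer(rng_seed))
  soa <- spec$train_duration + spec$iti
  n_blocks <- length(rates)
  total <- n_blocks * spec$n_standard + spec$n_oddball
  # interleave: sample which global slots carry an oddball
  odd_slots <- sort(sample.int(total, spec$n_oddball))
  is_odd <- rep(FALSE, total)
  is_odd[odd_slots] <- TRUE
  # assign slots to blocks so each block holds exactly n_standard standards
  block_id <- integer(total)
  b <- 1L; n_std_seen <- 0L
  for (i in seq_len(total)) {
    block_id[i] <- b
    if (!is_odd[i]) {
      n_std_seen <- n_std_seen + 1L
      if (n_std_seen == spec$n_standard && b < n_blocks) { b <- b + 1L; n_std_seen <- 0L }
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_blocks), function(bk) {
    idx <- which(block_id == bk)
    data.frame(block = bk, rate = rates[bk], trial = seq_along(idx),
               onset = (seq_along(idx) - 1) * soa,
               oddball = is_odd[idx])
  }))
  out$code <- ifelse(out$oddball, paste0("oddball", out$rate), paste0("assr", out$rate))
  out[, c("block", "rate", "trial", "onset", "code", "oddball")]
}
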
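#' Write a recording to EDF with an events sidecar
#'
#' Writes the continuous signal as 16-bit EDF (European Data Format,
#' physical units microvolts, one data record per second) and the event
#' table as a tab-separated sidecar `<stem>_events.tsv` with columns
#' `onset_sample` (0-based), `duration` (samples), `code`. Because EDF
#' stores whole data records, the final record is zero-padded; the true
#' sample count is recorded in the header's reserved field and restored by
#' [read_edf()]. Samples round-trip to within one 16-bit quantization step
#' of the per-channel physical range.
#'
#' @param recording An [eeg_recording()]. `fs` must be a whole number.
#' @param path Output path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(recording$channel_labels) == 0) stop("empty channel list")
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  dat <- recording$data
  n_ch <- nrow(dat); n_samp <- ncol(dat)
  n_rec <- ceiling(n_samp / fs)

  pad_field <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = -width, flag = "-")
  }
  # physical scaling per channel
  pmin_ <- apply(dat, 1, min); pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))                                  # version
  wr(pad_field("X X X X", 80))                           # patient id
  wr(pad_field("Startdate X X X X", 80))                 # recording id
  wr(pad_field("01.01.00", 8)); wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (1 + n_ch), 8))                     # header bytes
  wr(pad_field(sprintf("GASSR n=%d", n_samp), 44))       # reserved: true length
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))                                  # record duration, s
  wr(pad_field(n_ch, 4))
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  fields <- list(function(i) recording$channel_labels[i],
                 function(i) "",
                 function(i) "uV",
                 function(i) sprintf("%.6g", pmin_[i]),
                 function(i) sprintf("%.6g", pmax_[i]),
                 function(i) dmin, function(i) dmax,
                 function(i) "",
                 function(i) fs,
                 function(i) "")
  for (k in seq_along(fields)) {
    for (i in seq_len(n_ch)) wr(pad_field(fields[[k]](i), widths[k]))
  }

  # digitize: d = round((x - pmin)/(pmax-pmin)*(dmax-dmin)) + dmin
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- matrix(0, n_ch, n_rec * fs)
  padded[, seq_len(n_samp)] <- dat
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(n_ch)) {
      d <- as.integer(round((padded[i, idx] - pmin_[i]) * scale[i])) + dmin
      writeBin(d, con, size = 2, endian = "little")
    }
  }

  ev <- recording$events
  if (is.null(ev)) ev <- data.frame(onset_sample = integer(), duration = integer(),
                                    code = character())
  utils::write.table(ev, events_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

events_path <- function(edf_path) {
  sub("\\.edf$", "_events.tsv", edf_path, ignore.case = TRUE)
}

#' Read an EDF recording and its events sidecar
#'
#' Parses the 16-bit EDF written by [write_edf()] (and plain EDF files with
#' a uniform per-signal sampling rate). Events are restored from the
#' `<stem>_events.tsv` sidecar when present.
#'
#' @param path Path to the `.edf` file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  num_field <- function(s, name) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("malformed EDF header: field '", name, "' is not numeric ('", s, "')")
    v
  }
  rd(8)                          # version
  rd(80); rd(80); rd(8); rd(8)   # ids, date, time
  header_bytes <- num_field(rd(8), "header bytes")
  reserved <- rd(44)
  n_rec <- num_field(rd(8), "number of data records")
  rec_dur <- num_field(rd(8), "record duration")
  n_sig <- as.integer(num_field(rd(4), "number of signals"))
  if (n_sig < 1) stop("malformed EDF header: field 'number of signals' must be >= 1")

  rd_sig <- function(w) vapply(seq_len(n_sig), function(i) rd(w), character(1))
  labels <- rd_sig(16)
  rd_sig(80)                     # transducer
  rd_sig(8)                      # physical dimension
  pmin_ <- as.numeric(rd_sig(8)); pmax_ <- as.numeric(rd_sig(8))
  dmin <- as.numeric(rd_sig(8)); dmax <- as.numeric(rd_sig(8))
  if (anyNA(pmin_) || anyNA(pmax_)) stop("malformed EDF header: field 'physical min/max' is not numeric")
  if (anyNA(dmin) || anyNA(dmax)) stop("malformed EDF header: field 'digital min/max' is not numeric")
  rd_sig(80)                     # prefiltering
  spr <- as.integer(as.numeric(rd_sig(8)))
  if (anyNA(spr)) stop("malformed EDF header: field 'samples per record' is not numeric")
  rd_sig(32)
  if (length(unique(spr)) != 1) stop("read_edf supports a uniform sampling rate only")
  fs <- spr[1] / rec_dur

  total <- n_rec * spr[1]
  dat <- matrix(0, n_sig, total)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr[1] + seq_len(spr[1])
    for (i in seq_len(n_sig)) {
      d <- readBin(con, "integer", spr[1], size = 2, signed = TRUE, endian = "little")
      dat[i, idx] <- pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    }
  }
  m <- regmatches(reserved, regexec("GASSR n=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) {
    n_true <- as.integer(m[2])
    dat <- dat[, seq_len(n_true), drop = FALSE]
  }

  evp <- events_path(path)
  events <- NULL
  if (file.exists(evp)) {
    events <- utils::read.delim(evp, stringsAsFactors = FALSE)
    if (nrow(events) && any(events$onset_sample >= ncol(dat))) {
      stop("event onset_sample at or beyond n_samples (", ncol(dat),
           "): intervals are half-open [0, n_samples)")
    }
  }
  eeg_recording(data = dat, fs = fs, channel_labels = labels, events = events)
}
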
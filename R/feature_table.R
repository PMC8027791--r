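#' Build a validated feature table
#'
#' The long-format measurement table consumed by the statistics stage: one
#' row per (subject, dose condition, timepoint, measure), with the subject's
#' pretreatment-baseline value of the same measure attached to every
#' post-dose row. Measure names are free-form (EEG scores and metabolite
#' analytes pass through the same contract).
#'
#' @param df Data frame with columns `subject_id`, `dose`, `timepoint`,
#'   `measure`, `value`, and `baseline_value` (NA allowed only on
#'   `timepoint == "baseline"` rows).
#' @return The validated data frame (class `feature_table`).
#' @export
feature_table <- function(df) {
  need <- c("subject_id", "dose", "timepoint", "measure", "value", "baseline_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  key <- interaction(df$subject_id, df$dose, df$timepoint, df$measure, drop = TRUE)
  if (anyDuplicated(key)) {
    dups <- unique(as.character(key[duplicated(key)]))
    stop("duplicated (subject, dose, timepoint, measure) keys: ",
         paste(utils::head(dups, 5), collapse = "; "))
  }
  post <- df$timepoint != "baseline"
  bad <- post & !is.finite(df$baseline_value)
  if (any(bad)) {
    off <- unique(paste(df$subject_id[bad], df$dose[bad], df$measure[bad], sep = "/"))
    stop("missing baseline_value for non-baseline rows: ",
         paste(utils::head(off, 5), collapse = "; "),
         if (length(off) > 5) " ..." else "")
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write a feature table to CSV
#'
#' UTF-8, header row, period decimal separator.
#'
#' @param rows A [feature_table()] (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  rows <- feature_table(rows)
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()] (or any CSV with
#'   the declared header).
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  feature_table(df)
}

#' Attach baseline values to a long measurement table
#'
#' Convenience for simulator output: takes rows without `baseline_value`,
#' looks up each (subject, dose, measure)'s `timepoint == "baseline"` row,
#' and attaches its value to the post-dose rows.
#'
#' @param df Data frame with `subject_id`, `dose`, `timepoint`, `measure`,
#'   `value`.
#' @return A [feature_table()].
#' @export
attach_baseline <- function(df) {
  base <- df[df$timepoint == "baseline", ]
  key <- function(d) paste(d$subject_id, d$dose, d$measure, sep = "\r")
  lookup <- stats::setNames(base$value, key(base))
  df$baseline_value <- unname(lookup[key(df)])
  df$baseline_value[df$timepoint == "baseline"] <- NA_real_
  feature_table(df)
}
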
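#' Write a trial table to delimited text
#'
#' Tab-delimited, header row mandatory, missing values as empty fields,
#' seconds with 4 decimals. Columns: `session`, `index`, `type`,
#' `fp_s`, `ssd_s`, `rt_s`, `outcome` and, when present, `pstop`.
#'
#' @param subject an `sst_subject` or a trial data frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(subject, path) {
  trials <- if (inherits(subject, "sst_subject")) subject$trials else subject
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.4f", x))
  out <- data.frame(session = trials$session, index = trials$index,
                    type = trials$type, fp_s = fmt(trials$fp),
                    ssd_s = fmt(trials$ssd), rt_s = fmt(trials$rt),
                    outcome = trials$outcome, stringsAsFactors = FALSE)
  if (!is.null(trials$pstop)) out$pstop <- sprintf("%.6f", trials$pstop)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#'
#' @param path input file.
#' @return Trial data frame with columns `session`, `index`, `type`,
#'   `fp`, `ssd`, `rt`, `outcome` (and `pstop` if present), times in
#'   seconds.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  out <- data.frame(session = df$session, index = df$index,
                    type = df$type, fp = df$fp_s, ssd = df$ssd_s,
                    rt = df$rt_s, outcome = df$outcome,
                    stringsAsFactors = FALSE)
  if (!is.null(df$pstop)) out$pstop <- df$pstop
  out
}

#' Write an ROI series set to delimited text
#'
#' Tab-delimited with columns `session`, `volume` and one column per
#' ROI.
#'
#' @param series an `sst_roi_series` or `preproc_series`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_roi_series <- function(series, path) {
  x <- series$x
  ses <- series$session
  vol <- stats::ave(seq_along(ses), ses, FUN = seq_along)
  out <- data.frame(session = ses, volume = vol, x,
                    stringsAsFactors = FALSE)
  utils::write.table(format(out, digits = 8, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ROI series set written by [write_roi_series()]
#'
#' @param path input file.
#' @return List with `x` (matrix) and `session` (row labels), suitable
#'   for [preprocess_series()] after splitting by session.
#' @export
read_roi_series <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("session", "volume")),
                    drop = FALSE])
  structure(list(x = x, session = df$session, task = NULL),
            class = "sst_roi_series")
}
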
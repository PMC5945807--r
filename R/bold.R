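#' Simulate four-ROI BOLD series for one subject
#'
#' Forward model for the construct ROIs (stop-signal anticipation,
#' motor preparation, goRT slowing, goRT speeding): each ROI carries an
#' HRF-convolved event response scaled by its modulator amplitude —
#' P(Stop) and fore-period of go-success trials at trial onsets for the
#' first two ROIs, go RT at go-signal onsets with opposite signs for
#' the slowing and speeding ROIs — plus VAR(1) noise whose lag-1
#' coupling matrix plants the directed connectivity structure of the
#' neural profile. Sessions are generated independently and
#' concatenated with recorded boundaries.
#'
#' @param behavior an `sst_subject` covering all sessions.
#' @param neural a [neural_profile()].
#' @param task a [task_config()]; taken from the subject if omitted.
#' @param seed integer seed.
#' @return An object of class `sst_roi_series`: list with `x` (volumes
#'   x 4 matrix, columns `roi_pstop`, `roi_fp`, `roi_slow`,
#'   `roi_speed`), `session` (row labels) and `task`.
#' @export
simulate_roi_bold <- function(behavior, neural, task = NULL, seed = NULL) {
  stopifnot(inherits(behavior, "sst_subject"), inherits(neural, "sst_neural"))
  if (is.null(task)) task <- behavior$task
  if (!is.null(seed)) set.seed(seed)

  ev <- event_table(behavior, task)
  dF <- build_design(ev, "F1", task, orthogonalize = FALSE,
                     derivatives = FALSE)
  dG <- build_design(ev, "G", task, orthogonalize = FALSE,
                     derivatives = FALSE)
  col_sum <- function(design, lab) {
    hit <- sub("^ses[0-9]+_", "", colnames(design$X)) == lab
    if (!any(hit)) return(numeric(nrow(design$X)))
    rowSums(design$X[, hit, drop = FALSE])
  }
  amp <- neural$pm_amplitudes
  signal <- cbind(
    roi_pstop = amp[["pstop"]] * col_sum(dF, "GS_x_pstop"),
    roi_fp    = amp[["fp"]] * col_sum(dF, "GS_x_fp"),
    roi_slow  = amp[["slow"]] * col_sum(dG, "GS_x_rt"),
    roi_speed = -amp[["speed"]] * col_sum(dG, "GS_x_rt")
  )

  A <- neural$var_coupling
  nvol <- task$volumes_per_session
  noise <- matrix(0, nrow(signal), 4)
  row0 <- 0L
  for (ss in seq_len(task$n_sessions)) {
    burn <- 50L
    e <- matrix(stats::rnorm((nvol + burn) * 4), ncol = 4) %*%
      diag(neural$noise_sd)
    z <- matrix(0, nvol + burn, 4)
    for (t in 2:(nvol + burn)) z[t, ] <- A %*% z[t - 1, ] + e[t, ]
    noise[row0 + seq_len(nvol), ] <- z[burn + seq_len(nvol), ]
    row0 <- row0 + nvol
  }
  x <- signal + noise
  colnames(x) <- c("roi_pstop", "roi_fp", "roi_slow", "roi_speed")
  structure(list(x = x, session = dF$session, task = task,
                 preset = neural$preset),
            class = "sst_roi_series")
}

#' @export
print.sst_roi_series <- function(x, ...) {
  cat(sprintf("ROI BOLD series: %d volumes x %d ROIs, %d session(s)%s\n",
              nrow(x$x), ncol(x$x), length(unique(x$session)),
              if (!is.null(x$preset)) sprintf(" (preset %s)", x$preset) else ""))
  invisible(x)
}
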
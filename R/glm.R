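#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma response peaking at 6 s minus a gamma
#' undershoot peaking at 16 s at ratio 1/6, both with unit dispersion,
#' supported on 0-32 s and normalised to unit peak. The temporal
#' derivative is its finite-difference gradient.
#'
#' @param dt sampling interval of the kernel, seconds.
#' @return List with `t`, `hrf`, `dhrf` and `dt`.
#' @export
canonical_hrf <- function(dt) {
  stopifnot(dt > 0)
  t <- seq(0, 32, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  n <- length(h)
  d <- (c(h[-1], 0) - c(0, h[-n])) / (2 * dt)   # central difference
  list(t = t, hrf = h, dhrf = d, dt = dt)
}

#' Serially orthogonalize a set of regressors
#'
#' Residualises each column against all preceding columns in declared
#' order (sequential least-squares projection); the first column is
#' unchanged. This reproduces the convention by which later parametric
#' modulators only receive variance not attributable to earlier ones.
#'
#' @param x numeric matrix whose columns are regressors, in order.
#' @return Matrix of the same dimension with orthogonalized columns.
#' @export
serial_orthogonalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) return(x)
  for (j in 2:ncol(x)) {
    prev <- x[, 1:(j - 1), drop = FALSE]
    keep <- apply(prev, 2, function(v) sum(v^2) > 1e-12)
    if (!any(keep)) next
    fit <- stats::lm.fit(prev[, keep, drop = FALSE], x[, j])
    x[, j] <- fit$residuals
    if (sum(x[, j]^2) < 1e-12 * max(1, sum(prev^2)))
      warning(sprintf("column %d is numerically zero after orthogonalization", j),
              call. = FALSE)
  }
  x
}

# Event timings for a subject: cumulative trial onsets within a session
# (trial onset, fore-period, go signal, response window, then ITI).
event_onsets <- function(trials, task) {
  out <- numeric(nrow(trials))
  for (s in unique(trials$session)) {
    idx <- which(trials$session == s)
    dur <- trials$fp[idx] + task$response_window + task$iti
    out[idx] <- c(0, cumsum(dur[-length(dur)]))
  }
  out
}

#' Build the event table for the GLM of one subject
#'
#' Extracts per-event onsets (both trial onset and go-signal onset),
#' condition labels and the modulator values used by the F and G model
#' designs: P(Stop), fore-period, SSD, RT and the unsigned prediction
#' error UPE = |s - P(Stop)| with s = 1 on stop trials.
#'
#' @param subject an `sst_subject`, or its trial table (must carry a
#'   `pstop` column).
#' @param task a [task_config()]; taken from the subject if omitted.
#' @return Data frame with columns `session`, `trial_onset`,
#'   `go_onset`, `condition`, `pstop`, `fp`, `ssd`, `rt`, `upe`.
#' @export
event_table <- function(subject, task = NULL) {
  if (inherits(subject, "sst_subject")) {
    if (is.null(task)) task <- subject$task
    trials <- subject$trials
  } else trials <- subject
  stopifnot(!is.null(task), "pstop" %in% names(trials))
  onset <- event_onsets(trials, task)
  s <- as.integer(trials$type == "stop")
  data.frame(session = trials$session,
             trial_onset = onset,
             go_onset = onset + trials$fp,
             condition = trials$outcome,
             pstop = trials$pstop, fp = trials$fp,
             ssd = trials$ssd, rt = trials$rt,
             upe = abs(s - trials$pstop),
             stringsAsFactors = FALSE)
}

# Parametric-modulator orderings of each design variant.
# F models lock to trial onsets (anticipation/preparation); the G model
# locks to go-signal onsets (response-related activity).
variant_spec <- function(variant) {
  switch(variant,
    F1 = list(onset = "trial_onset",
              pms = list(GS = c("pstop", "fp"), GE = character(0),
                         SS = c("ssd", "pstop", "fp"),
                         SE = c("ssd", "pstop", "fp"))),
    F2 = list(onset = "trial_onset",
              pms = list(GS = c("fp", "pstop"), GE = character(0),
                         SS = c("ssd", "fp", "pstop"),
                         SE = c("ssd", "fp", "pstop"))),
    G  = list(onset = "go_onset",
              pms = list(GS = c("upe", "rt"), GE = character(0),
                         SS = c("ssd", "upe"),
                         SE = c("ssd", "upe", "rt"))),
    stop(sprintf("unknown design variant '%s'", variant), call. = FALSE))
}

#' Build an ROI-level design matrix
#'
#' Constructs the event-related design for one subject and one model
#' variant. Each outcome condition contributes an onset regressor
#' (delta sticks convolved with the canonical HRF), its temporal
#' derivative, and the variant's parametric modulators in declared
#' order: `"F1"` puts P(Stop) before FP, `"F2"` puts FP before
#' P(Stop) (both locked to trial onsets); `"G"` locks to go-signal
#' onsets with UPE and RT modulators. Modulators are mean-centred per
#' session before being multiplied into the sticks and convolved. The
#' design is built at a microtime resolution of TR/16, sampled at
#' volume midpoints, then serially orthogonalized within condition
#' (onset regressor first, modulators in order), and completed with a
#' discrete-cosine drift basis up to a 1/128 Hz cutoff and a constant
#' per session.
#'
#' @param events event table from [event_table()].
#' @param variant `"F1"`, `"F2"` or `"G"`.
#' @param task a [task_config()].
#' @param orthogonalize serially orthogonalize modulators within
#'   condition (default TRUE, the standard convention).
#' @param derivatives include temporal-derivative regressors.
#' @return An object of class `sst_design`: list with the matrix `X`
#'   (volumes x regressors, named columns), `session` (row labels) and
#'   `variant`.
#' @export
build_design <- function(events, variant = c("F1", "F2", "G"),
                         task = task_config(), orthogonalize = TRUE,
                         derivatives = TRUE) {
  variant <- match.arg(variant)
  vs <- variant_spec(variant)
  dt <- task$tr / 16
  ker <- canonical_hrf(dt)
  nvol <- task$volumes_per_session
  nmicro <- nvol * 16L
  sample_idx <- 16L * seq_len(nvol) - 8L    # volume midpoints

  conv_sample <- function(stick) {
    z <- stats::convolve(stick, rev(ker$hrf), type = "open")[seq_len(nmicro)]
    z[sample_idx]
  }
  conv_sample_d <- function(stick) {
    z <- stats::convolve(stick, rev(ker$dhrf), type = "open")[seq_len(nmicro)]
    z[sample_idx]
  }

  sessions <- seq_len(task$n_sessions)
  blocks <- list(); session_row <- integer(0)
  for (ss in sessions) {
    ev <- events[events$session == ss, , drop = FALSE]
    cols <- list()
    for (cond in c("GS", "GE", "SS", "SE")) {
      e <- ev[ev$condition == cond, , drop = FALSE]
      if (nrow(e) == 0L) next
      onsets <- e[[vs$onset]]
      bins <- floor(onsets / dt) + 1L
      ok <- bins >= 1L & bins <= nmicro
      e <- e[ok, , drop = FALSE]; bins <- bins[ok]
      if (nrow(e) == 0L) next
      stick <- numeric(nmicro); stick[bins] <- stick[bins] + 1
      grp <- list()
      grp[[cond]] <- conv_sample(stick)
      if (derivatives) grp[[paste0(cond, "_td")]] <- conv_sample_d(stick)
      for (pm in vs$pms[[cond]]) {
        val <- e[[pm]]
        if (any(!is.finite(val))) next
        if (length(val) < 2L || stats::sd(val) == 0) next
        v <- val - mean(val)                  # centre per session
        mstick <- numeric(nmicro); mstick[bins] <- mstick[bins] + v
        grp[[paste0(cond, "_x_", pm)]] <- conv_sample(mstick)
      }
      if (orthogonalize) {
        nm <- names(grp)
        ord <- c(cond, setdiff(nm, c(cond, paste0(cond, "_td"))))
        m <- serial_orthogonalize(do.call(cbind, grp[ord]))
        for (j in seq_along(ord)) grp[[ord[j]]] <- m[, j]
      }
      cols <- c(cols, grp)
    }
    # drift: cosine basis up to 1/128 Hz, plus the session constant
    span <- nvol * task$tr
    k_max <- floor(2 * span / 128)
    tt <- (seq_len(nvol) - 0.5) / nvol
    for (k in seq_len(k_max))
      cols[[paste0("dct", k)]] <- cos(pi * k * tt)
    cols[["const"]] <- rep(1, nvol)
    m <- do.call(cbind, cols)
    colnames(m) <- paste0("ses", ss, "_", names(cols))
    blocks[[as.character(ss)]] <- m
    session_row <- c(session_row, rep(ss, nvol))
  }
  nall <- length(session_row)
  X <- matrix(0, nall, 0)
  row0 <- 0L
  for (b in blocks) {
    pad <- matrix(0, nall, ncol(b), dimnames = list(NULL, colnames(b)))
    pad[row0 + seq_len(nrow(b)), ] <- b
    X <- cbind(X, pad)
    row0 <- row0 + nrow(b)
  }
  structure(list(X = X, session = session_row, variant = variant,
                 task = task),
            class = "sst_design")
}

#' @export
print.sst_design <- function(x, ...) {
  cat(sprintf("SST design (%s model): %d volumes x %d regressors, %d session(s)\n",
              x$variant, nrow(x$X), ncol(x$X), length(unique(x$session))))
  invisible(x)
}

#' Fit an ROI time series with AR(1) correction
#'
#' Ordinary least squares, followed by estimation of the lag-1
#' autocorrelation of the residuals (within sessions), exact AR(1)
#' prewhitening of both sides, and a refit. Betas are reported from the
#' prewhitened fit.
#'
#' @param series numeric vector, one value per volume (all sessions
#'   concatenated, matching the design rows).
#' @param design an `sst_design`.
#' @return An object of class `sst_glm_fit`: list with `betas` (named),
#'   `rho`, `residuals` (whitened), `design`.
#' @export
fit_glm_ar1 <- function(series, design) {
  X <- design$X
  if (length(series) != nrow(X))
    stop("series length must equal the number of design rows", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  res <- qr.resid(qrX, series)
  same <- design$session[-1] == design$session[-length(series)]
  r1 <- res[-1][same]; r0 <- res[-length(res)][same]
  denom <- sum(r0^2)
  rho <- if (denom < 1e-10 * max(1, sum(series^2))) 0 else sum(r1 * r0) / denom
  rho <- max(min(rho, 0.99), -0.99)

  # exact AR(1) whitening per session: first row scaled, rest differenced
  wy <- series; wX <- X
  for (ss in unique(design$session)) {
    idx <- which(design$session == ss)
    f <- idx[1]; rest <- idx[-1]
    wy[rest] <- series[rest] - rho * series[rest - 1]
    wX[rest, ] <- X[rest, ] - rho * X[rest - 1, ]
    wy[f] <- sqrt(1 - rho^2) * series[f]
    wX[f, ] <- sqrt(1 - rho^2) * X[f, ]
  }
  fit <- stats::lm.fit(wX, wy)
  betas <- fit$coefficients
  betas[is.na(betas)] <- 0
  structure(list(betas = betas, rho = rho, residuals = fit$residuals,
                 design = design),
            class = "sst_glm_fit")
}

#' @export
print.sst_glm_fit <- function(x, ...) {
  cat(sprintf("ROI GLM fit (%s model): %d betas, AR(1) rho = %.3f\n",
              x$design$variant, length(x$betas), x$rho))
  invisible(x)
}

#' Contrast weights by modulator name
#'
#' Builds a weight vector over the design columns from a named
#' specification such as `c("GS_x_rt" = 1)`; the weight on each name is
#' split evenly over the sessions in which the regressor appears.
#'
#' @param design an `sst_design`.
#' @param spec named numeric vector; names are column labels without
#'   the session prefix.
#' @return Numeric weight vector of length `ncol(design$X)`.
#' @export
contrast_weights <- function(design, spec) {
  nm <- colnames(design$X)
  base <- sub("^ses[0-9]+_", "", nm)
  w <- numeric(length(nm))
  for (lab in names(spec)) {
    hit <- base == lab
    if (!any(hit))
      stop(sprintf("no design column matches '%s'", lab), call. = FALSE)
    w[hit] <- w[hit] + spec[[lab]] / sum(hit)
  }
  w
}

#' Contrast effect of a fitted GLM
#'
#' @param fit an `sst_glm_fit`.
#' @param weights numeric weight vector over the betas, e.g. from
#'   [contrast_weights()].
#' @return The weighted sum of betas.
#' @export
contrast_effect <- function(fit, weights) {
  if (length(weights) != length(fit$betas))
    stop("weights length must equal the number of betas", call. = FALSE)
  sum(weights * fit$betas)
}
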
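#' Stop-signal task configuration
#'
#' Parameters of the stop-signal task (SST) as presented to a subject:
#' session structure, fore-period distribution, stop-trial frequency and
#' the staircase that titrates the stop-signal delay (SSD), plus the
#' imaging sampling grid used by the BOLD forward model.
#'
#' Defaults describe a four-session task of about 100 trials per session
#' with a 2 s inter-trial interval, fore-periods uniform on 1-5 s, one
#' quarter stop trials, a staircase starting at 200 ms moving in 67 ms
#' steps, a 1 s response window, and 295 retained volumes per session at
#' TR = 2 s.
#'
#' @param n_sessions number of task sessions.
#' @param trials_per_session trials in each session.
#' @param iti inter-trial interval, seconds.
#' @param fp_min,fp_max bounds of the uniform fore-period distribution,
#'   seconds.
#' @param stop_fraction probability that a trial carries a stop signal.
#' @param ssd_init initial stop-signal delay, seconds.
#' @param ssd_step staircase step, seconds.
#' @param response_window maximum time allowed for a response, seconds.
#' @param tr repetition time of the BOLD sampling grid, seconds.
#' @param volumes_per_session retained BOLD volumes per session.
#' @return An object of class `sst_task` (a validated list).
#' @examples
#' task_config()
#' task_config(n_sessions = 1, trials_per_session = 50)
#' @export
task_config <- function(n_sessions = 4L, trials_per_session = 100L,
                        iti = 2, fp_min = 1, fp_max = 5,
                        stop_fraction = 0.25, ssd_init = 0.200,
                        ssd_step = 0.067, response_window = 1,
                        tr = 2, volumes_per_session = 295L) {
  task <- list(n_sessions = as.integer(n_sessions),
               trials_per_session = as.integer(trials_per_session),
               iti = iti, fp_min = fp_min, fp_max = fp_max,
               stop_fraction = stop_fraction, ssd_init = ssd_init,
               ssd_step = ssd_step, response_window = response_window,
               tr = tr, volumes_per_session = as.integer(volumes_per_session))
  class(task) <- "sst_task"
  validate_task(task)
  task
}

validate_task <- function(task) {
  stopifnot(inherits(task, "sst_task"))
  with(task, {
    if (n_sessions < 1L || trials_per_session < 1L)
      stop("n_sessions and trials_per_session must be positive", call. = FALSE)
    if (!(stop_fraction >= 0 && stop_fraction < 1))
      stop("stop_fraction must lie in [0, 1)", call. = FALSE)
    if (!(fp_min < fp_max)) stop("fp_min must be < fp_max", call. = FALSE)
    if (ssd_step <= 0) stop("ssd_step must be positive", call. = FALSE)
    if (ssd_init < 0 || ssd_init > response_window)
      stop("ssd_init must lie in [0, response_window]", call. = FALSE)
    if (tr <= 0 || volumes_per_session < 1L)
      stop("invalid imaging grid", call. = FALSE)
  })
  invisible(task)
}

#' @export
print.sst_task <- function(x, ...) {
  cat("Stop-signal task configuration\n")
  cat(sprintf("  %d session(s) x %d trials, ITI %g s\n",
              x$n_sessions, x$trials_per_session, x$iti))
  cat(sprintf("  fore-period ~ U(%g, %g) s, stop fraction %.2f\n",
              x$fp_min, x$fp_max, x$stop_fraction))
  cat(sprintf("  staircase: SSD start %.0f ms, step %.0f ms, window %g s\n",
              1000 * x$ssd_init, 1000 * x$ssd_step, x$response_window))
  cat(sprintf("  imaging: TR %g s, %d volumes/session\n",
              x$tr, x$volumes_per_session))
  invisible(x)
}

#' Bayesian observer parameters
#'
#' Parameters of the dynamic Bayesian model of stop-signal expectation.
#' The observer believes the stop-signal rate `r` on trial k stays equal
#' to its previous value with probability `alpha` and is re-drawn from a
#' Beta prior with mean `pm` and concentration `scale` with probability
#' `1 - alpha`. Beliefs are held on a discrete grid of `grid_size`
#' midpoints in (0, 1).
#'
#' @param alpha belief-persistence probability in \[0, 1\].
#' @param pm prior mean of the stop-signal rate, in (0, 1).
#' @param scale prior concentration (Beta shape), positive; the prior is
#'   Beta(pm * scale, (1 - pm) * scale).
#' @param grid_size number of grid points (>= 100).
#' @return An object of class `sst_observer` (a validated list).
#' @examples
#' observer_params()
#' observer_params(alpha = 1, pm = 0.5, scale = 2)
#' @export
observer_params <- function(alpha = 0.8, pm = 0.25, scale = 10,
                            grid_size = 1000L) {
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!(pm > 0 && pm < 1)) stop("pm must lie in (0, 1)", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (grid_size < 100L) stop("grid_size must be >= 100", call. = FALSE)
  structure(list(alpha = alpha, pm = pm, scale = scale,
                 grid_size = as.integer(grid_size)),
            class = "sst_observer")
}

#' @export
print.sst_observer <- function(x, ...) {
  cat(sprintf("Bayesian observer: alpha = %g, pm = %g, scale = %g, grid = %d\n",
              x$alpha, x$pm, x$scale, x$grid_size))
  invisible(x)
}

#' Generative subject profile
#'
#' Parameters of a simulated race-model subject. The go-process finish
#' time on each trial is
#' `rt_base + beta_pstop * P(Stop) + beta_fp * (FP - mean FP) + noise`,
#' with Gaussian noise of standard deviation `rt_noise_sd`. On stop
#' trials the go process races an inhibitory process of fixed latency
#' `ssrt_true` starting at the SSD. Subjects labelled `"SEQ"` carry a
#' positive `beta_pstop` (go RT lengthens with stop expectation); the
#' `"nSEQ"` profile sets it to zero. `beta_fp` is negative for both
#' groups: longer fore-periods speed responding.
#'
#' @param group `"SEQ"` or `"nSEQ"`.
#' @param rt_base baseline go finish time, seconds.
#' @param beta_pstop RT increase per unit P(Stop), seconds (>= 0).
#' @param beta_fp RT change per second of fore-period, seconds (< 0).
#' @param rt_noise_sd trial-to-trial Gaussian RT noise, seconds.
#' @param ssrt_true latency of the stopping process, seconds.
#' @param observer observer parameters used for the subject's own
#'   (subjective) P(Stop); defaults to [observer_params()].
#' @param omission_rate probability that a go trial draws no response.
#' @return An object of class `sst_profile`.
#' @export
subject_profile <- function(group = c("SEQ", "nSEQ"),
                            rt_base = 0.42, beta_pstop = NULL,
                            beta_fp = -0.017, rt_noise_sd = 0.12,
                            ssrt_true = 0.21,
                            observer = observer_params(),
                            omission_rate = 0.012) {
  group <- match.arg(group)
  if (is.null(beta_pstop)) beta_pstop <- if (group == "SEQ") 0.8 else 0
  if (beta_pstop < 0) stop("beta_pstop must be >= 0", call. = FALSE)
  if (beta_fp >= 0) stop("beta_fp must be negative", call. = FALSE)
  if (rt_noise_sd < 0) stop("rt_noise_sd must be >= 0", call. = FALSE)
  if (ssrt_true <= 0) stop("ssrt_true must be positive", call. = FALSE)
  if (omission_rate < 0 || omission_rate >= 1)
    stop("omission_rate must lie in [0, 1)", call. = FALSE)
  structure(list(group = group, rt_base = rt_base, beta_pstop = beta_pstop,
                 beta_fp = beta_fp, rt_noise_sd = rt_noise_sd,
                 ssrt_true = ssrt_true, observer = observer,
                 omission_rate = omission_rate),
            class = "sst_profile")
}

#' Cohort specification
#'
#' Sizes, task and per-group generative parameter distributions for a
#' simulated cohort. The default split of 81 subjects with a sequential
#' effect and 35 without reproduces the study cohort; the default
#' profile distributions are calibrated so that group behavioural
#' summaries approximate the observed ones (median goRT near 616/675 ms,
#' stop success near 51%, fore-period effect r near -0.16 in both
#' groups).
#'
#' Each entry of `profile_distributions` is a list with elements `mean`
#' and `sd` (Gaussian draw, truncated at `lower`) for the fields
#' `rt_base`, `beta_pstop`, `beta_fp`, `rt_noise_sd`, `ssrt_true`.
#'
#' @param n_seq,n_nseq group sizes.
#' @param task a [task_config()].
#' @param observer observer parameters shared by subjects.
#' @param profile_distributions per-group parameter distributions; see
#'   Details. Defaults via `default_profile_distributions()`.
#' @param seed integer seed for cohort generation.
#' @return An object of class `sst_cohort_spec`.
#' @export
cohort_spec <- function(n_seq = 81L, n_nseq = 35L, task = task_config(),
                        observer = observer_params(),
                        profile_distributions = default_profile_distributions(),
                        seed = 1L) {
  if (n_seq < 0 || n_nseq < 0) stop("group sizes must be >= 0", call. = FALSE)
  validate_task(task)
  structure(list(n_seq = as.integer(n_seq), n_nseq = as.integer(n_nseq),
                 task = task, observer = observer,
                 profile_distributions = profile_distributions,
                 seed = as.integer(seed)),
            class = "sst_cohort_spec")
}

#' Default generative parameter distributions per group
#'
#' Gaussian (truncated) distributions from which subject profiles are
#' drawn. Means are set so that simulated group summaries land near the
#' observed behavioural table: SEQ baseline RT 416 ms plus about 200 ms
#' of mean P(Stop)-driven slowing (slope 0.8 s per unit P(Stop) at a
#' mean stop expectation of 0.25) gives a median goRT near 616 ms; the
#' slope also makes the sequential effect detectable within a subject,
#' since the observer's trial-wise P(Stop) fluctuates with a standard
#' deviation of only about 0.04. nSEQ baseline is 675 ms with no
#' P(Stop) slope; stopping latency 207 vs 241 ms; a common fore-period
#' slope of -17 ms/s over U(1,5) s fore-periods with ~120 ms residual
#' RT noise yields a within-subject fore-period correlation near -0.16
#' in both groups.
#'
#' @return A named list with elements `SEQ` and `nSEQ`.
#' @export
default_profile_distributions <- function() {
  list(
    SEQ = list(
      rt_base    = list(mean = 0.416, sd = 0.115, lower = 0.20),
      beta_pstop = list(mean = 0.800, sd = 0.150, lower = 0.45),
      beta_fp    = list(mean = -0.017, sd = 0.010, upper = -0.001),
      rt_noise_sd = list(mean = 0.120, sd = 0.020, lower = 0.06),
      ssrt_true  = list(mean = 0.207, sd = 0.036, lower = 0.08)
    ),
    nSEQ = list(
      rt_base    = list(mean = 0.675, sd = 0.125, lower = 0.25),
      beta_pstop = list(mean = 0, sd = 0, lower = 0),
      beta_fp    = list(mean = -0.017, sd = 0.010, upper = -0.001),
      rt_noise_sd = list(mean = 0.120, sd = 0.020, lower = 0.06),
      ssrt_true  = list(mean = 0.241, sd = 0.048, lower = 0.08)
    )
  )
}

#' Neural generative profile for ROI BOLD simulation
#'
#' Describes how four construct ROIs (stop-signal anticipation, motor
#' preparation, goRT slowing, goRT speeding) are generated: event-locked
#' responses scaled by parametric-modulator amplitudes plus VAR(1) noise
#' with a planted directed coupling structure.
#'
#' Presets plant the directed connection patterns reported for the two
#' behavioural groups: `"SEQ_fig4"` couples P(Stop) and FP reciprocally,
#' P(Stop) to goRT slowing, and slowing to speeding; `"nSEQ_fig4"`
#' couples FP to P(Stop) (one-way), P(Stop) to slowing, FP to speeding,
#' and speeding to slowing. `"null"` plants no coupling.
#'
#' @param preset `"SEQ_fig4"`, `"nSEQ_fig4"` or `"null"`.
#' @param coupling lag-1 coefficient planted on each directed
#'   connection.
#' @param self lag-1 self-coupling (diagonal of the VAR matrix).
#' @param noise_sd innovation standard deviation, length 1 or 4.
#' @param pm_amplitudes named numeric vector of BOLD effect sizes for
#'   the per-ROI modulators `pstop`, `fp`, `slow`, `speed`.
#' @param var_coupling optional explicit 4 x 4 lag-1 matrix
#'   (row = target, column = source); overrides the preset pattern.
#' @return An object of class `sst_neural` with elements
#'   `var_coupling`, `noise_sd`, `pm_amplitudes`, `preset`.
#' @export
neural_profile <- function(preset = c("SEQ_fig4", "nSEQ_fig4", "null"),
                           coupling = 0.3, self = 0.2, noise_sd = 1,
                           pm_amplitudes = c(pstop = 0.5, fp = 0.5,
                                             slow = 0.5, speed = 0.5),
                           var_coupling = NULL) {
  preset <- match.arg(preset)
  rois <- c("pstop", "fp", "slow", "speed")
  if (is.null(var_coupling)) {
    A <- diag(self, 4)
    plant <- function(src, tgt) A[match(tgt, rois), match(src, rois)] <<- coupling
    if (preset == "SEQ_fig4") {
      plant("pstop", "fp"); plant("fp", "pstop")   # reciprocal P(Stop) <-> FP
      plant("pstop", "slow")                        # P(Stop) -> slowing
      plant("slow", "speed")                        # slowing -> speeding
    } else if (preset == "nSEQ_fig4") {
      plant("fp", "pstop")                          # FP -> P(Stop), one-way
      plant("pstop", "slow")                        # P(Stop) -> slowing
      plant("fp", "speed")                          # FP -> speeding
      plant("speed", "slow")                        # speeding -> slowing
    }
    var_coupling <- A
  }
  var_coupling <- as.matrix(var_coupling)
  if (!all(dim(var_coupling) == c(4, 4)))
    stop("var_coupling must be 4 x 4", call. = FALSE)
  if (max(Mod(eigen(var_coupling, only.values = TRUE)$values)) >= 1)
    stop("var_coupling is unstable (spectral radius >= 1)", call. = FALSE)
  noise_sd <- rep_len(noise_sd, 4)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  amp <- c(pstop = 0, fp = 0, slow = 0, speed = 0)
  amp[names(pm_amplitudes)] <- pm_amplitudes
  dimnames(var_coupling) <- list(rois, rois)
  structure(list(preset = preset, var_coupling = var_coupling,
                 noise_sd = noise_sd, pm_amplitudes = amp,
                 roi_names = rois),
            class = "sst_neural")
}

# Draw one value from a truncated-Gaussian distribution spec
draw_param <- function(d) {
  x <- stats::rnorm(1, d$mean, d$sd)
  if (!is.null(d$lower)) x <- max(x, d$lower)
  if (!is.null(d$upper)) x <- min(x, d$upper)
  x
}
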
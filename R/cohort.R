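#' Generate a go/stop trial sequence
#'
#' Draws the trial types and fore-periods for a full task: stop trials
#' are independent Bernoulli draws at the configured stop fraction and
#' fore-periods are uniform on `[fp_min, fp_max]`.
#'
#' @param task a [task_config()].
#' @param seed integer seed; the same seed reproduces the sequence.
#' @return Data frame with columns `session`, `index` (within-session
#'   trial number), `type` (`"go"`/`"stop"`) and `fp` (seconds).
#' @export
generate_trial_sequence <- function(task = task_config(), seed = NULL) {
  validate_task(task)
  if (!is.null(seed)) set.seed(seed)
  n <- task$n_sessions * task$trials_per_session
  data.frame(
    session = rep(seq_len(task$n_sessions), each = task$trials_per_session),
    index = rep(seq_len(task$trials_per_session), task$n_sessions),
    type = ifelse(stats::runif(n) < task$stop_fraction, "stop", "go"),
    fp = stats::runif(n, task$fp_min, task$fp_max),
    stringsAsFactors = FALSE
  )
}

#' One staircase step of the stop-signal delay
#'
#' After a successful stop (SS) the SSD increases by one step, making
#' stopping harder; after a failed stop (SE) it decreases by one step.
#' The result is clamped to `[floor, ceiling]`.
#'
#' @param ssd current stop-signal delay, seconds.
#' @param outcome `"SS"` or `"SE"`.
#' @param step staircase step, seconds.
#' @param floor,ceiling clamp bounds, seconds.
#' @return The next SSD in seconds.
#' @examples
#' staircase_update(0.200, "SS")  # 0.267
#' staircase_update(0.200, "SE")  # 0.133
#' @export
staircase_update <- function(ssd, outcome, step = 0.067, floor = 0,
                             ceiling = 1) {
  if (!outcome %in% c("SS", "SE"))
    stop("staircase_update applies to stop outcomes (SS/SE) only",
         call. = FALSE)
  out <- if (outcome == "SS") ssd + step else ssd - step
  min(max(out, floor), ceiling)
}

#' Simulate one race-model subject on the stop-signal task
#'
#' Runs a subject through a trial sequence. On every trial the
#' subject's subjective P(Stop) is the Bayesian observer's predictive
#' mean over the subject's own trial history. The go-process finish
#' time is the linear RT model of the profile plus Gaussian noise; on
#' stop trials it races an inhibitory process of latency `ssrt_true`
#' starting at the current SSD (response emitted iff the go process
#' finishes first). The SSD follows the staircase across stop trials,
#' clamped to `[0, response_window]`. Go responses slower than the
#' response window, and a small fraction of spontaneous omissions, are
#' recorded as go errors (GE) without an RT.
#'
#' @param profile a [subject_profile()].
#' @param sequence trial sequence as from [generate_trial_sequence()];
#'   generated from `task` if `NULL`.
#' @param task a [task_config()].
#' @param seed integer seed.
#' @return An object of class `sst_subject`: list with `trials` (data
#'   frame: `session`, `index`, `type`, `fp`, `ssd`, `rt`, `outcome`,
#'   `pstop`), `profile` and `task`.
#' @export
simulate_subject <- function(profile, sequence = NULL, task = task_config(),
                             seed = NULL) {
  stopifnot(inherits(profile, "sst_profile"))
  validate_task(task)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence)) sequence <- generate_trial_sequence(task)
  n <- nrow(sequence)
  obs <- profile$observer
  prior <- init_prior(obs)
  support <- prior$support
  prior_mass <- prior$mass
  post <- prior_mass
  alpha <- obs$alpha

  fp_mean <- (task$fp_min + task$fp_max) / 2
  noise <- stats::rnorm(n, 0, profile$rt_noise_sd)
  omit <- stats::runif(n) < profile$omission_rate

  ssd_cur <- task$ssd_init
  ssd <- rep(NA_real_, n)
  rt <- rep(NA_real_, n)
  outcome <- character(n)
  pstop <- numeric(n)

  for (k in seq_len(n)) {
    pred <- if (k == 1L) prior_mass else alpha * post + (1 - alpha) * prior_mass
    pred <- pred / sum(pred)
    pk <- sum(support * pred)
    pstop[k] <- pk

    t_go <- profile$rt_base + profile$beta_pstop * pk +
      profile$beta_fp * (sequence$fp[k] - fp_mean) + noise[k]

    if (sequence$type[k] == "stop") {
      ssd[k] <- ssd_cur
      if (t_go < ssd_cur + profile$ssrt_true &&
          t_go <= task$response_window && !omit[k]) {
        outcome[k] <- "SE"
        rt[k] <- t_go
      } else {
        outcome[k] <- "SS"
      }
      ssd_cur <- staircase_update(ssd_cur, outcome[k], task$ssd_step,
                                  0, task$response_window)
      s_k <- 1
    } else {
      if (omit[k] || t_go > task$response_window) {
        outcome[k] <- "GE"
      } else {
        outcome[k] <- "GS"
        rt[k] <- t_go
      }
      s_k <- 0
    }

    lik <- if (s_k == 1) support else 1 - support
    post <- pred * lik
    post <- post / sum(post)
  }

  trials <- data.frame(session = sequence$session, index = sequence$index,
                       type = sequence$type, fp = sequence$fp,
                       ssd = ssd, rt = rt, outcome = outcome,
                       pstop = pstop, stringsAsFactors = FALSE)
  structure(list(trials = trials, profile = profile, task = task),
            class = "sst_subject")
}

#' @export
print.sst_subject <- function(x, ...) {
  tab <- table(factor(x$trials$outcome, levels = c("GS", "GE", "SS", "SE")))
  cat(sprintf("Simulated SST subject (%s): %d trials\n",
              x$profile$group, nrow(x$trials)))
  cat(sprintf("  GS %d  GE %d  SS %d  SE %d\n",
              tab["GS"], tab["GE"], tab["SS"], tab["SE"]))
  invisible(x)
}

#' Generate a simulated cohort
#'
#' Draws subject profiles from the per-group distributions of the
#' cohort specification and simulates each subject on its own trial
#' sequence. Group labels record the generative profile (`"SEQ"` has a
#' positive P(Stop) slope); observed classification may differ for a
#' small fraction of subjects, as in real data.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `sst_cohort`: list of `sst_subject` with
#'   attribute `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "sst_cohort_spec"))
  set.seed(spec$seed)
  groups <- c(rep("SEQ", spec$n_seq), rep("nSEQ", spec$n_nseq))
  subject_seeds <- sample.int(.Machine$integer.max - 1L,
                              length(groups) + 1L)
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    d <- spec$profile_distributions[[g]]
    set.seed(subject_seeds[i])
    prof <- subject_profile(
      group = g,
      rt_base = draw_param(d$rt_base),
      beta_pstop = if (g == "SEQ") draw_param(d$beta_pstop) else 0,
      beta_fp = draw_param(d$beta_fp),
      rt_noise_sd = draw_param(d$rt_noise_sd),
      ssrt_true = draw_param(d$ssrt_true),
      observer = spec$observer
    )
    subjects[[i]] <- simulate_subject(prof, task = spec$task)
  }
  structure(subjects, class = "sst_cohort", spec = spec)
}

#' @export
print.sst_cohort <- function(x, ...) {
  g <- vapply(x, function(s) s$profile$group, character(1))
  cat(sprintf("Simulated SST cohort: %d subjects (%d SEQ, %d nSEQ profiles)\n",
              length(x), sum(g == "SEQ"), sum(g == "nSEQ")))
  invisible(x)
}
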
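#' Partition a stop-signal delay series into monotone runs
#'
#' Groups consecutive SSDs into maximal monotonically increasing or
#' decreasing runs. A direction reversal terminates the current run and
#' starts the next at the same value (shared endpoint); ties (equal
#' consecutive values, possible after clamping) extend the current run.
#'
#' @param ssd_series numeric vector of SSDs in presentation order
#'   (length >= 2).
#' @return An object of class `ssd_runs`: list with `runs` (list of
#'   numeric vectors) and `turning_points` (indices into the series
#'   where runs begin).
#' @examples
#' partition_runs(c(200, 267, 334, 267, 200, 267, 334))
#' @export
partition_runs <- function(ssd_series) {
  n <- length(ssd_series)
  if (n < 2L)
    stop("need at least 2 SSD values to partition into runs", call. = FALSE)
  starts <- 1L
  dir <- 0
  for (i in 2:n) {
    d <- sign(ssd_series[i] - ssd_series[i - 1])
    if (d == 0) next                       # tie extends the current run
    if (dir != 0 && d != dir) starts <- c(starts, i - 1L)  # reversal
    dir <- d
  }
  ends <- c(starts[-1], n)
  runs <- mapply(function(a, b) ssd_series[a:b], starts, ends,
                 SIMPLIFY = FALSE)
  structure(list(runs = runs, turning_points = starts), class = "ssd_runs")
}

#' Critical stop-signal delay (mid-run estimate)
#'
#' Estimates the SSD at which stopping succeeds half the time. SSDs are
#' partitioned into monotone runs; the mid-run values are the medians of
#' every second run (the 2nd, 4th, ...), and the critical SSD is their
#' mean. For staircases longer than about 30 stop trials this tracks
#' the maximum-likelihood estimate of the 50% point closely.
#'
#' @param ssd_series numeric vector of stop-trial SSDs in presentation
#'   order.
#' @return Critical SSD in the units of the input.
#' @examples
#' critical_ssd(c(200, 267, 334, 267, 200, 267, 334))  # 267
#' @export
critical_ssd <- function(ssd_series) {
  part <- partition_runs(ssd_series)
  if (length(part$runs) < 2L)
    stop("need at least 2 runs to form a mid-run estimate", call. = FALSE)
  even <- seq(2L, length(part$runs), by = 2L)
  mids <- vapply(part$runs[even], stats::median, numeric(1))
  mean(mids)
}

#' Stop-signal reaction time
#'
#' SSRT under the race model: median go RT minus the critical SSD.
#' Both arguments must be in the same units.
#'
#' @param median_gort median go-trial RT.
#' @param crit_ssd critical SSD.
#' @return SSRT; a warning is raised if it comes out negative.
#' @examples
#' ssrt(616, 409)  # 207
#' @export
ssrt <- function(median_gort, crit_ssd) {
  if (!is.finite(median_gort) || !is.finite(crit_ssd))
    stop("median goRT and critical SSD must be finite", call. = FALSE)
  out <- median_gort - crit_ssd
  if (out < 0) warning("negative SSRT estimate", call. = FALSE)
  out
}

#' Pearson trial-wise effect on go RT
#'
#' Pearson correlation between a per-trial quantity (P(Stop) for the
#' sequential effect, fore-period for the FP effect) and go-success RT,
#' with the two-tailed p value from the t distribution on n - 2 df.
#'
#' @param x per-trial values (GS trials only).
#' @param rt go RTs for the same trials.
#' @return List with elements `r`, `p` and `n`.
#' @export
correlation_effect <- function(x, rt) {
  keep <- is.finite(x) & is.finite(rt)
  x <- x[keep]; rt <- rt[keep]
  n <- length(x)
  if (n < 10L) stop("need at least 10 paired trials", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(rt) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, rt, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Classify a subject as SEQ or nSEQ
#'
#' A subject shows a sequential effect (SEQ) when the P(Stop)-goRT
#' correlation is significant and positive: higher stop expectation
#' slows responding.
#'
#' @param seq_p two-tailed p value of the sequential-effect correlation.
#' @param seq_r the correlation itself.
#' @param alpha_level significance level.
#' @return `"SEQ"` or `"nSEQ"`.
#' @export
classify_subject <- function(seq_p, seq_r, alpha_level = 0.05) {
  if (is.finite(seq_p) && is.finite(seq_r) &&
      seq_p < alpha_level && seq_r > 0) "SEQ" else "nSEQ"
}

#' Behavioural metrics for one subject
#'
#' Computes the full behavioural summary from a trial table: go and
#' stop-success rates, median go RT, critical SSD, SSRT, median
#' stop-error RT (SERT), sequential effect (P(Stop) x goRT) and
#' fore-period effect (FP x goRT) with the observed SEQ/nSEQ
#' classification. Rates are percentages; times are reported in ms.
#'
#' @param trials trial table with columns `type`, `fp`, `ssd`, `rt`,
#'   `outcome` and `pstop` (see [add_pstop()]), or an `sst_subject`.
#' @param alpha_level significance level for classification.
#' @return One-row data frame of class `sst_metrics`.
#' @export
subject_metrics <- function(trials, alpha_level = 0.05) {
  if (inherits(trials, "sst_subject")) trials <- trials$trials
  go <- trials[trials$type == "go", ]
  st <- trials[trials$type == "stop", ]
  gs <- go[go$outcome == "GS", ]
  se <- st[st$outcome == "SE", ]

  seq_eff <- correlation_effect(gs$pstop, gs$rt)
  fp_eff <- correlation_effect(gs$fp, gs$rt)
  cssd <- critical_ssd(st$ssd) * 1000
  med_gort <- stats::median(gs$rt) * 1000

  out <- data.frame(
    go_rate = 100 * nrow(gs) / nrow(go),
    ss_rate = 100 * sum(st$outcome == "SS") / nrow(st),
    median_gort = med_gort,
    critical_ssd = cssd,
    ssrt = ssrt(med_gort, cssd),
    sert = stats::median(se$rt, na.rm = TRUE) * 1000,
    seq_r = seq_eff$r, seq_p = seq_eff$p,
    fp_r = fp_eff$r, fp_p = fp_eff$p,
    group = classify_subject(seq_eff$p, seq_eff$r, alpha_level),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sst_metrics", class(out))
  out
}

#' Behavioural metrics for every subject of a cohort
#'
#' @param cohort an `sst_cohort` (or list of `sst_subject`).
#' @param alpha_level significance level for classification.
#' @return Data frame with one row per subject, including the
#'   generative `profile_group` where available.
#' @export
cohort_metrics <- function(cohort, alpha_level = 0.05) {
  rows <- lapply(seq_along(cohort), function(i) {
    m <- subject_metrics(cohort[[i]], alpha_level)
    m$subject <- i
    m$profile_group <- if (inherits(cohort[[i]], "sst_subject"))
      cohort[[i]]$profile$group else NA_character_
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pooled-variance two-sample t from group summaries
pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Group behavioural summary (performance table)
#'
#' Mean and standard deviation of every behavioural measure per group,
#' with a pooled-variance two-sample t test (two-tailed) comparing the
#' groups on each row, in the layout of a task-performance table.
#'
#' @param metrics per-subject metrics as from [cohort_metrics()].
#' @param group_col which column defines the groups: the observed
#'   classification (`"group"`, default) or the generative label
#'   (`"profile_group"`).
#' @return Data frame of class `sst_group_summary`: one row per
#'   measure with per-group `mean`/`sd`, `t`, `p` and group sizes.
#' @export
group_summary <- function(metrics, group_col = "group") {
  g <- metrics[[group_col]]
  lv <- c("SEQ", "nSEQ")
  if (any(table(factor(g, levels = lv)) < 2))
    stop("need at least 2 subjects per group", call. = FALSE)
  vars <- c(go_rate = "GR (%)", ss_rate = "SS (%)",
            median_gort = "Median goRT (ms)", critical_ssd = "Critical SSD (ms)",
            ssrt = "SSRT (ms)", sert = "SERT (ms)",
            seq_r = "Sequential effect (r)", fp_r = "FP effect (r)")
  rows <- lapply(names(vars), function(v) {
    x1 <- metrics[[v]][g == "SEQ"]; x2 <- metrics[[v]][g == "nSEQ"]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    tt <- pooled_t(mean(x1), stats::sd(x1), length(x1),
                   mean(x2), stats::sd(x2), length(x2))
    data.frame(measure = vars[[v]],
               seq_mean = mean(x1), seq_sd = stats::sd(x1),
               nseq_mean = mean(x2), nseq_sd = stats::sd(x2),
               t = tt$t, p = tt$p, n_seq = length(x1), n_nseq = length(x2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sst_group_summary", class(out))
  out
}

#' @export
print.sst_group_summary <- function(x, digits = 3, ...) {
  cat(sprintf("SST performance, SEQ (n = %d) vs nSEQ (n = %d)\n",
              x$n_seq[1], x$n_nseq[1]))
  df <- data.frame(
    Measure = x$measure,
    SEQ = sprintf("%.3g ± %.3g", x$seq_mean, x$seq_sd),
    nSEQ = sprintf("%.3g ± %.3g", x$nseq_mean, x$nseq_sd),
    t = round(x$t, 3), p = signif(x$p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-tailed Fisher's exact test for two proportions
#'
#' Exact hypergeometric tail probability comparing `k1/n1` with
#' `k2/n2`, one-tailed in the direction of the larger observed
#' proportion. Used to compare the number of subjects per group showing
#' a significant connection.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @return The one-tailed p value.
#' @examples
#' fisher_exact_one_tailed(38, 81, 12, 35)  # 0.145
#' @export
fisher_exact_one_tailed <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  m <- k1 + k2          # total successes
  n <- n1 + n2 - m      # total failures
  if (k1 / n1 >= k2 / n2) {
    # P(X >= k1) drawing n1 from the margin
    stats::phyper(k1 - 1, m, n, n1, lower.tail = FALSE)
  } else {
    stats::phyper(k1, m, n, n1, lower.tail = TRUE)
  }
}
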
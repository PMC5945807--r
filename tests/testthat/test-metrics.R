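test_that("SSD runs are maximal monotone segments with shared endpoints", {
  p <- partition_runs(c(200, 267, 334, 267, 200, 267, 334))
  expect_equal(p$runs, list(c(200, 267, 334), c(334, 267, 200),
                            c(200, 267, 334)))
  expect_length(partition_runs(c(1, 2, 3, 4))$runs, 1)
  expect_equal(partition_runs(c(200, 133, 200))$runs,
               list(c(200, 133), c(133, 200)))
  # ties extend the current run
  expect_length(partition_runs(c(1, 2, 2, 3))$runs, 1)
  expect_error(partition_runs(200), "at least 2")
  # runs reconstruct the series (shared endpoints dropped on joins)
  s <- c(200, 267, 334, 267, 200, 267, 334)
  rec <- p$runs[[1]]
  for (r in p$runs[-1]) rec <- c(rec, r[-1])
  expect_equal(rec, s)
})

test_that("critical SSD is the mean of every second run's median", {
  expect_equal(critical_ssd(c(200, 267, 334, 267, 200, 267, 334)), 267)
  expect_equal(critical_ssd(rep(c(200, 267), 20)), 233.5)
  expect_error(critical_ssd(c(1, 2, 3)), "at least 2 runs")
})

test_that("mid-run critical SSD tracks the maximum-likelihood 50% point", {
  # staircase over a known go-finish distribution; the ML logistic X50
  # fitted to (ssd, responded) data is the independent reference
  set.seed(31)
  n <- 400
  ssd <- numeric(n); resp <- logical(n)
  cur <- 0.2
  for (i in seq_len(n)) {
    ssd[i] <- cur
    t_go <- rnorm(1, 0.6, 0.1)
    resp[i] <- t_go < cur + 0.2          # stop failure: response emitted
    cur <- staircase_update(cur, if (resp[i]) "SE" else "SS")
  }
  fit <- suppressWarnings(glm(resp ~ ssd, family = binomial()))
  x50 <- -coef(fit)[1] / coef(fit)[2]
  expect_lt(abs(critical_ssd(ssd) - x50), 0.020)
})

test_that("SSRT is median goRT minus critical SSD", {
  expect_equal(ssrt(616, 409), 207)
  expect_equal(ssrt(500, 500), 0)
  expect_warning(ssrt(300, 400), "negative")
  expect_error(ssrt(NA, 1), "finite")
})

test_that("race-model SSRT is recovered for a simulated subject", {
  task <- task_config(n_sessions = 4, trials_per_session = 400)
  s <- quick_subject(seed = 17, task = task, ssrt_true = 0.2)
  m <- subject_metrics(s)
  expect_gt(m$ssrt, 170)
  expect_lt(m$ssrt, 230)
})

test_that("correlation effect gives Pearson r with a t-based p value", {
  x <- seq_len(50)
  eff <- correlation_effect(x, 2 * x)
  expect_equal(eff$r, 1)
  expect_lt(eff$p, 1e-10)
  expect_error(correlation_effect(rep(1, 20), rnorm(20)), "variance")
  expect_error(correlation_effect(1:5, 1:5), "at least 10")

  set.seed(13)
  rs <- replicate(100, correlation_effect(rnorm(1000), rnorm(1000))$r)
  expect_gte(mean(abs(rs) < 0.08), 0.95)
})

test_that("the sequential effect is detected in calibrated SEQ subjects", {
  hits <- vapply(1:20, function(i) {
    s <- quick_subject(seed = 900 + i, rt_noise_sd = 0.1)
    m <- subject_metrics(s)
    m$seq_p < 0.05 && m$seq_r > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("classification requires a significant positive correlation", {
  expect_equal(classify_subject(0.01, 0.2), "SEQ")
  expect_equal(classify_subject(0.30, 0.05), "nSEQ")
  expect_equal(classify_subject(0.01, -0.2), "nSEQ")
})

test_that("group summary reproduces pooled two-sample t statistics", {
  # two identical groups: all t = 0, p = 1
  base <- data.frame(go_rate = 98, ss_rate = 51, median_gort = 600,
                     critical_ssd = 390, ssrt = 210, sert = 540,
                     seq_r = 0.2, seq_p = 0.01, fp_r = -0.16, fp_p = 0.01)
  same <- do.call(rbind, rep(list(base), 6))
  wiggle <- rep(c(-1, 1, 0), 2)           # identical pattern in each group
  for (v in names(base)) same[[v]] <- same[[v]] + wiggle
  same$group <- rep(c("SEQ", "nSEQ"), 3)
  gs <- group_summary(same)
  expect_true(all(abs(gs$t) < 1e-10))
  expect_true(all(gs$p > 0.999))

  # groups constructed with exactly the published summary moments
  mk <- function(n, m, s) { z <- rnorm(n); m + s * scale(z)[, 1] }
  set.seed(5)
  df <- data.frame(median_gort = c(mk(81, 616, 123), mk(35, 675, 132)),
                   group = rep(c("SEQ", "nSEQ"), c(81, 35)))
  for (v in setdiff(names(base), "median_gort")) df[[v]] <- rnorm(116)
  gs2 <- group_summary(df)
  # pooled t from the rounded summary moments (the unrounded data give
  # -2.3209; the summaries themselves pin -2.31946)
  t_gort <- gs2$t[gs2$measure == "Median goRT (ms)"]
  expect_equal(t_gort, -2.319455, tolerance = 1e-4)
  expect_error(group_summary(df[c(1, 82), ]), "at least 2")
})

test_that("one-tailed Fisher test matches the hypergeometric tail", {
  expect_equal(round(fisher_exact_one_tailed(38, 81, 12, 35), 3), 0.145)
  expect_lte(fisher_exact_one_tailed(30, 81, 20, 35), 0.036)
  expect_gt(fisher_exact_one_tailed(5, 10, 5, 10), 0.5)

  # cross-check against the independent exact test for small tables
  set.seed(9)
  for (i in 1:30) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    alt <- if (k1 / n1 >= k2 / n2) "greater" else "less"
    ref <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2),
                       alternative = alt)$p.value
    expect_equal(fisher_exact_one_tailed(k1, n1, k2, n2), ref,
                 tolerance = 1e-12)
  }
})

test_that("critical SSD uses only the stop-trial delay series", {
  s <- quick_subject(seed = 41)
  st <- s$trials[s$trials$type == "stop", ]
  expect_equal(subject_metrics(s)$critical_ssd, critical_ssd(st$ssd) * 1000)
})
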
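test_that("preprocessing detrends, normalizes and records boundaries", {
  set.seed(1)
  a <- matrix(rnorm(600), 300, 2)
  b <- matrix(rnorm(600), 300, 2)
  b[, 1] <- b[, 1] + seq(0, 5, length.out = 300)       # linear ramp
  ps <- preprocess_series(list(a, b))
  expect_equal(ps$session, rep(1:2, each = 300))
  for (s in 1:2) for (j in 1:2) {
    v <- ps$x[ps$session == s, j]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  expect_lt(abs(cor(ps$x[ps$session == 2, 1], 1:300)), 1e-10)
  expect_error(preprocess_series(list(cbind(rep(1, 100), rnorm(100)))),
               "constant")
})

test_that("the ADF test separates stationary noise from random walks", {
  set.seed(21)
  rej_white <- vapply(1:20, function(i)
    adf_test(rnorm(1000))$reject_unit_root, logical(1))
  expect_true(all(rej_white))
  rej_walk <- vapply(1:20, function(i)
    adf_test(cumsum(rnorm(1000)))$reject_unit_root, logical(1))
  expect_lte(mean(rej_walk), 0.10)
  expect_error(adf_test(rep(1, 100)), "constant")
  expect_error(adf_test(rnorm(10)), "short")
})

test_that("AIC selects the generative VAR order", {
  A1 <- neural_profile("SEQ_fig4", coupling = 0.4, self = 0.3)$var_coupling
  sel1 <- vapply(1:30, function(i)
    select_order_aic(make_var1_series(A1, n = 1000, seed = 100 + i), 6),
    integer(1))
  expect_gte(mean(sel1 == 1), 0.9)

  # strong VAR(3): coupling only at lag 3
  sel3 <- vapply(1:10, function(i) {
    set.seed(200 + i)
    n <- 1200; burn <- 60
    z <- matrix(0, n + burn, 2)
    e <- matrix(rnorm((n + burn) * 2), ncol = 2)
    for (t in 4:(n + burn))
      z[t, ] <- c(0.6 * z[t - 3, 2], -0.6 * z[t - 3, 1]) + e[t, ]
    select_order_aic(preprocess_series(list(z[burn + 1:n, ])), 6)
  }, integer(1))
  expect_gte(mean(sel3 == 3), 0.9)

  ps <- make_var1_series(A1, n = 300, seed = 3)
  expect_equal(select_order_aic(ps, 1), 1L)
})

test_that("VAR coefficients are recovered and nulls stay near zero", {
  A <- matrix(c(0.4, 0.25, -0.2, 0.5), 2, 2, byrow = TRUE)
  ps <- make_var1_series(A, n = 4000, seed = 7)
  fit <- fit_var(ps, 1)
  expect_lt(sqrt(mean((fit$A[[1]] - A)^2)), 0.05)

  ps0 <- preprocess_series(list(matrix(rnorm(8000), 4000, 2)))
  fit0 <- fit_var(ps0, 1)
  se <- 1 / sqrt(4000)
  expect_lt(max(abs(fit0$A[[1]][row(A) != col(A)])), 4 * se)
  expect_error(fit_var(preprocess_series(list(matrix(rnorm(20), 10, 2))), 8),
               "not enough")
})

test_that("Geweke F matches the analytic value for a planted coupling", {
  set.seed(11)
  n <- 4000
  x <- rnorm(n); e <- rnorm(n)
  y <- c(0, 0.5 * x[-n]) + e
  ps <- preprocess_series(list(cbind(x = x, y = y)))
  expect_lt(abs(geweke_f(ps, "x", "y", 1) - log(1.25)), 0.03)
  expect_lt(geweke_f(ps, "y", "x", 1), 0.01)
  expect_error(geweke_f(ps, "x", "x", 1), "differ")
  expect_error(geweke_f(ps, "q", "y", 1), "unknown")
})

test_that("surrogates preserve each ROI's spectrum but break coupling", {
  A <- matrix(c(0.3, 0.5, 0, 0.3), 2, 2, byrow = TRUE)  # x drives y
  ps <- make_var1_series(A, n = 1000, seed = 13, sessions = 2)
  su <- make_surrogate(ps, seed = 14)
  for (s in 1:2) {
    idx <- ps$session == s
    for (j in 1:2) {
      expect_equal(mean(su$x[idx, j]), mean(ps$x[idx, j]), tolerance = 1e-8)
      expect_equal(sd(su$x[idx, j]), sd(ps$x[idx, j]), tolerance = 1e-8)
      expect_equal(Mod(fft(su$x[idx, j])), Mod(fft(ps$x[idx, j])),
                   tolerance = 1e-8)
    }
  }
  f_orig <- geweke_f(ps, 2, 1, 1)     # source column 2 drives column 1
  f_surr <- vapply(1:20, function(i)
    geweke_f(make_surrogate(ps, seed = 100 + i), 2, 1, 1), numeric(1))
  expect_gt(f_orig, 0.1)
  expect_lt(median(f_surr), 0.01)
})

test_that("group GCA flags exactly the planted connection sets", {
  task <- task_config()
  mk_group <- function(preset, seed0) {
    lapply(1:6, function(i) {
      s <- simulate_subject(subject_profile("SEQ"), task = task,
                            seed = seed0 + i)
      simulate_roi_bold(s, neural_profile(preset), seed = seed0 + 50 + i)
    })
  }
  planted <- list(
    SEQ_fig4 = c("roi_pstop->roi_fp", "roi_fp->roi_pstop",
                 "roi_pstop->roi_slow", "roi_slow->roi_speed"),
    nSEQ_fig4 = c("roi_fp->roi_pstop", "roi_pstop->roi_slow",
                  "roi_fp->roi_speed", "roi_speed->roi_slow"))
  for (preset in names(planted)) {
    g <- group_gca(mk_group(preset, if (preset == "SEQ_fig4") 300 else 400),
                   p_max = 4, n_perm = 150, seed = 5)
    flagged <- with(g$connections,
                    paste0(source, "->", target)[significant])
    expect_setequal(flagged, planted[[preset]])
  }
  # nSEQ: FP -> P(Stop) without the reverse
  g <- group_gca(mk_group("nSEQ_fig4", 400), p_max = 4, n_perm = 150,
                 seed = 5)
  cn <- g$connections
  expect_true(cn$significant[cn$source == "roi_fp" & cn$target == "roi_pstop"])
  expect_false(cn$significant[cn$source == "roi_pstop" & cn$target == "roi_fp"])
})

test_that("null cohorts produce no flags and a calibrated permutation null", {
  task <- task_config(n_sessions = 2)
  ser <- lapply(1:5, function(i) {
    s <- simulate_subject(subject_profile("nSEQ"), task = task,
                          seed = 600 + i)
    simulate_roi_bold(s, neural_profile("null", pm_amplitudes =
                                          c(pstop = 0, fp = 0, slow = 0,
                                            speed = 0)),
                      seed = 650 + i)
  })
  g <- group_gca(ser, p_max = 3, n_perm = 150, seed = 8)
  expect_equal(sum(g$connections$significant), 0)
  # observed group means sit inside the body of their null
  expect_true(all(g$connections$p_perm > 0.01))
})

test_that("single-subject GCA reduces to a subject-level permutation test", {
  A <- matrix(c(0.3, 0.4, 0, 0.3), 2, 2, byrow = TRUE)
  ps <- make_var1_series(A, n = 500, seed = 17)
  expect_warning(g <- group_gca(list(ps), orders = 1L, n_perm = 99,
                                seed = 3),
                 "permutations")
  expect_equal(unname(g$connections$group_mean_f), unname(g$subject_f[1, ]))
  expect_equal(g$connections$n_subj_significant,
               as.integer(g$connections$group_mean_f >
                            g$connections$f_critical))
})

test_that("subject counts feed the one-tailed Fisher comparison", {
  A <- matrix(c(0.3, 0.4, 0, 0.3), 2, 2, byrow = TRUE)
  g1 <- group_gca(lapply(1:3, function(i)
    make_var1_series(A, n = 400, seed = 20 + i)), orders = rep(1L, 3),
    n_perm = 120, seed = 1)
  g2 <- group_gca(lapply(1:3, function(i)
    make_var1_series(diag(0.3, 2), n = 400, seed = 30 + i)),
    orders = rep(1L, 3), n_perm = 120, seed = 2)
  counts <- subject_connection_counts(g1)
  expect_named(counts, paste0(g1$connections$source, "->",
                              g1$connections$target))
  cmp <- connection_count_comparison(g1, g2)
  expect_equal(nrow(cmp), 2)
  i <- which(cmp$source == "roi2" & cmp$target == "roi1")
  expect_equal(cmp$p_one_tailed[i],
               fisher_exact_one_tailed(cmp$k1[i], 3, cmp$k2[i], 3))
})
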
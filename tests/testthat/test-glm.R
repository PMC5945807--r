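# Helper: adjust the fore-period modulator of a (single-session, go-only)
# event table so its HRF-convolved design column is exactly orthogonal,
# after removing the onset-regressor component, to the P(Stop) column.
orthogonalized_fp_events <- function(ev, task) {
  d0 <- build_design(ev, "F1", task, orthogonalize = FALSE)
  m <- d0$X[, "ses1_GS"]
  pcol <- d0$X[, "ses1_GS_x_pstop"]
  fcol <- d0$X[, "ses1_GS_x_fp"]
  pperp <- qr.resid(qr(cbind(m)), pcol)
  fperp <- qr.resid(qr(cbind(m)), fcol)
  lambda <- sum(fperp * pperp) / sum(pperp^2)
  ev$fp <- ev$fp - lambda * (ev$pstop - mean(ev$pstop))
  ev
}

go_only_subject <- function(seed = 23) {
  task <- task_config(n_sessions = 1, trials_per_session = 90,
                      stop_fraction = 0)
  s <- simulate_subject(subject_profile("SEQ", omission_rate = 0),
                        task = task, seed = seed)
  list(subject = s, task = task, events = event_table(s))
}

test_that("canonical HRF peaks near 5 s with a balanced derivative", {
  k <- canonical_hrf(0.1)
  expect_equal(k$t[which.max(k$hrf)], 5, tolerance = 0.2)
  expect_gt(sum(k$hrf) * k$dt, 0)
  expect_lt(abs(sum(k$dhrf) * k$dt), 0.05)
  expect_equal(max(k$hrf), 1)
})

test_that("serial orthogonalization projects later columns onto earlier residuals", {
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(serial_orthogonalize(x), x)          # already orthogonal
  dup <- cbind(x[, 1], x[, 1])
  expect_warning(out <- serial_orthogonalize(dup), "zero")
  expect_lt(max(abs(out[, 2])), 1e-10)
  # orthogonalization never changes the span: fitted values identical
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  f1 <- X %*% qr.coef(qr(X), y)
  Xo <- serial_orthogonalize(X)
  f2 <- Xo %*% qr.coef(qr(Xo), y)
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("design matrices carry the variant-specific modulator order", {
  s <- quick_subject(seed = 51, task = small_task(trials = 120))
  ev <- event_table(s)
  d1 <- build_design(ev, "F1", s$task)
  nm <- sub("^ses1_", "", colnames(d1$X))
  gs <- nm[grep("^GS_x_", nm)]
  expect_equal(gs, c("GS_x_pstop", "GS_x_fp"))
  ss <- nm[grep("^SS_x_", nm)]
  expect_equal(ss, c("SS_x_ssd", "SS_x_pstop", "SS_x_fp"))
  d2 <- build_design(ev, "F2", s$task)
  nm2 <- sub("^ses1_", "", colnames(d2$X))
  expect_equal(nm2[grep("^GS_x_", nm2)], c("GS_x_fp", "GS_x_pstop"))
  dg <- build_design(ev, "G", s$task)
  nmg <- sub("^ses1_", "", colnames(dg$X))
  expect_equal(nmg[grep("^GS_x_", nmg)], c("GS_x_upe", "GS_x_rt"))
  expect_equal(nmg[grep("^SE_x_", nmg)], c("SE_x_ssd", "SE_x_upe", "SE_x_rt"))
  expect_error(build_design(ev, "H", s$task))
})

test_that("an event-free design reduces to drift plus constant", {
  ev0 <- data.frame(session = integer(0), trial_onset = numeric(0),
                    go_onset = numeric(0), condition = character(0),
                    pstop = numeric(0), fp = numeric(0), ssd = numeric(0),
                    rt = numeric(0), upe = numeric(0))
  task <- task_config(n_sessions = 1)
  d <- build_design(ev0, "F1", task)
  nm <- sub("^ses1_", "", colnames(d$X))
  expect_true(all(grepl("^dct[0-9]+$|^const$", nm)))
  expect_equal(nrow(d$X), task$volumes_per_session)
})

test_that("the drift basis removes slow scanner drifts", {
  ev0 <- data.frame(session = integer(0), trial_onset = numeric(0),
                    go_onset = numeric(0), condition = character(0),
                    pstop = numeric(0), fp = numeric(0), ssd = numeric(0),
                    rt = numeric(0), upe = numeric(0))
  task <- task_config(n_sessions = 1)
  d <- build_design(ev0, "F1", task)
  tsec <- (seq_len(task$volumes_per_session) - 0.5) * task$tr
  for (period in c(400, 600, 1200)) {
    y <- sin(2 * pi * tsec / period + pi / 5)
    r <- qr.resid(qr(d$X), y)
    expect_lt(sum(r^2) / sum(y^2), 0.01)
  }
})

test_that("noiseless forward-model betas are recovered exactly", {
  task <- task_config(n_sessions = 1)
  s <- quick_subject(seed = 3, task = task)
  np <- neural_profile("null", noise_sd = 0,
                       pm_amplitudes = c(pstop = 0.7, fp = 0.4,
                                         slow = 0.5, speed = 0.3))
  b <- simulate_roi_bold(s, np, seed = 4)
  ev <- event_table(s)
  des <- build_design(ev, "F1", task, orthogonalize = FALSE)
  fit <- fit_glm_ar1(b$x[, "roi_pstop"], des)
  expect_equal(unname(fit$betas["ses1_GS_x_pstop"]), 0.7, tolerance = 1e-8)
  desG <- build_design(ev, "G", task, orthogonalize = FALSE)
  fitG <- fit_glm_ar1(b$x[, "roi_slow"], desG)
  expect_equal(unname(fitG$betas["ses1_GS_x_rt"]), 0.5, tolerance = 1e-8)
  fitSp <- fit_glm_ar1(b$x[, "roi_speed"], desG)
  expect_equal(unname(fitSp$betas["ses1_GS_x_rt"]), -0.3, tolerance = 1e-8)
})

test_that("betas stay unbiased under AR(1) noise", {
  task <- task_config(n_sessions = 1)
  s <- quick_subject(seed = 5, task = task)
  np <- neural_profile("null", noise_sd = 0,
                       pm_amplitudes = c(pstop = 0, fp = 1, slow = 0,
                                         speed = 0))
  clean <- simulate_roi_bold(s, np, seed = 6)$x[, "roi_fp"]
  des <- build_design(event_table(s), "F1", task, orthogonalize = FALSE)
  nvol <- length(clean)
  betas <- vapply(1:40, function(i) {
    set.seed(700 + i)
    ar <- as.numeric(stats::arima.sim(list(ar = 0.3), nvol, sd = 0.5))
    fit <- fit_glm_ar1(clean + ar, des)
    unname(fit$betas["ses1_GS_x_fp"])
  }, numeric(1))
  expect_lt(abs(mean(betas) - 1), 0.05)
  # the AR(1) coefficient itself is picked up
  set.seed(99)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.3), nvol, sd = 0.5))
  expect_equal(fit_glm_ar1(clean + ar, des)$rho, 0.3, tolerance = 0.12)
})

test_that("contrasts are linear and centered on zero under the null", {
  task <- task_config(n_sessions = 1)
  s <- quick_subject(seed = 7, task = task)
  des <- build_design(event_table(s), "G", task)
  w <- contrast_weights(des, c(GS_x_rt = 1))
  effects <- vapply(1:25, function(i) {
    set.seed(800 + i)
    contrast_effect(fit_glm_ar1(rnorm(nrow(des$X)), des), w)
  }, numeric(1))
  expect_lt(abs(mean(effects)), 3 * sd(effects) / sqrt(25))
  fit <- fit_glm_ar1(rnorm(nrow(des$X)), des)
  expect_equal(contrast_effect(fit, -w), -contrast_effect(fit, w))
  expect_error(contrast_effect(fit, w[-1]), "length")
  expect_error(contrast_weights(des, c(nonexistent = 1)), "matches")
})

test_that("modulator order does not matter once the columns are orthogonal", {
  go <- go_only_subject(seed = 23)
  ev <- orthogonalized_fp_events(go$events, go$task)
  d1 <- build_design(ev, "F1", go$task)
  d2 <- build_design(ev, "F2", go$task)
  set.seed(12)
  y <- 0.6 * d1$X[, "ses1_GS_x_pstop"] - 0.4 * d1$X[, "ses1_GS_x_fp"] +
    rnorm(nrow(d1$X), 0, 0.3)
  f1 <- fit_glm_ar1(y, d1); f2 <- fit_glm_ar1(y, d2)
  for (lab in c("GS_x_pstop", "GS_x_fp")) {
    c1 <- contrast_effect(f1, contrast_weights(d1, setNames(1, lab)))
    c2 <- contrast_effect(f2, contrast_weights(d2, setNames(1, lab)))
    expect_lt(abs(c1 - c2), 1e-6)
  }
})
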
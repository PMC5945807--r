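#' Preprocess ROI session series for Granger causality analysis
#'
#' Per session and per ROI: remove a linear trend, z-normalise, then
#' concatenate sessions and record their boundaries. All model fitting
#' downstream excludes lag windows that would span a session boundary.
#'
#' @param sessions a list of numeric matrices (time x ROI), one per
#'   session, or an `sst_roi_series` from [simulate_roi_bold()].
#' @return An object of class `preproc_series`: list with `x`
#'   (concatenated matrix), `session` (row labels) and `roi_names`.
#' @export
preprocess_series <- function(sessions) {
  if (inherits(sessions, "preproc_series")) return(sessions)
  if (inherits(sessions, "sst_roi_series"))
    sessions <- split.data.frame(sessions$x, sessions$session)
  stopifnot(is.list(sessions), length(sessions) >= 1)
  roi_names <- colnames(sessions[[1]])
  if (is.null(roi_names))
    roi_names <- paste0("roi", seq_len(ncol(sessions[[1]])))
  out <- list(); lab <- integer(0)
  for (i in seq_along(sessions)) {
    m <- as.matrix(sessions[[i]])
    if (ncol(m) < 2) stop("need at least 2 ROIs", call. = FALSE)
    t <- seq_len(nrow(m))
    for (j in seq_len(ncol(m))) {
      v <- stats::lm.fit(cbind(1, t), m[, j])$residuals  # detrend
      s <- stats::sd(v)
      if (s < 1e-12)
        stop(sprintf("ROI %d is constant within session %d", j, i),
             call. = FALSE)
      m[, j] <- v / s
    }
    out[[i]] <- m
    lab <- c(lab, rep(i, nrow(m)))
  }
  structure(list(x = do.call(rbind, out), session = lab,
                 roi_names = roi_names),
            class = "preproc_series")
}

#' @export
print.preproc_series <- function(x, ...) {
  cat(sprintf("Preprocessed ROI series: %d x %d, %d session(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$session))))
  invisible(x)
}

# Rows whose full lag window of length p lies inside one session.
lag_valid_rows <- function(session, p) {
  pos <- stats::ave(seq_along(session), session, FUN = seq_along)
  which(pos > p)
}

# Lagged regressor matrix for the given rows: [const, lag1 ROIs, ...,
# lagp ROIs]; also the column indices belonging to each source ROI.
lag_design <- function(x, rows, p) {
  m <- ncol(x)
  X <- matrix(1, length(rows), 1 + m * p)
  src_cols <- vector("list", m)
  for (lag in seq_len(p)) {
    cols <- 1 + (lag - 1) * m + seq_len(m)
    X[, cols] <- x[rows - lag, , drop = FALSE]
    for (j in seq_len(m)) src_cols[[j]] <- c(src_cols[[j]], cols[j])
  }
  list(X = X, src_cols = src_cols)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regresses the first difference on an intercept, the lagged level and
#' `lags` lagged differences; the t statistic of the lagged level is
#' compared with the 5% Dickey-Fuller critical value (constant, no
#' trend), interpolated over sample size. The unit-root null is
#' rejected (series judged stationary) when the statistic falls below
#' the critical value.
#'
#' @param series numeric vector (length >= 50).
#' @param lags number of lagged differences in the regression.
#' @return List with `statistic`, `critical` and `reject_unit_root`.
#' @export
adf_test <- function(series, lags = 1) {
  n <- length(series)
  if (n < 50) stop("series too short for the ADF test", call. = FALSE)
  if (stats::sd(series) < 1e-12)
    stop("constant series: ADF test degenerate", call. = FALSE)
  dy <- diff(series)
  t0 <- (lags + 1):(n - 1)
  X <- cbind(1, series[t0])
  for (k in seq_len(lags)) X <- cbind(X, dy[t0 - k])
  y <- dy[t0]
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfree <- length(y) - ncol(X)
  s2 <- sum(res^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(X)))
  tstat <- fit$coefficients[2] / sqrt(s2 * xtx_inv[2, 2])
  # 5% critical values, regression with constant (Dickey-Fuller / MacKinnon)
  sizes <- c(25, 50, 100, 250, 500, Inf)
  cvs <- c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86)
  cv <- stats::approx(sizes, cvs, xout = min(length(y), 500),
                      rule = 2)$y
  list(statistic = unname(tstat), critical = cv,
       reject_unit_root = unname(tstat < cv))
}

#' Select the VAR order by AIC
#'
#' Fits candidate orders 1..`p_max` on a common set of
#' boundary-respecting rows (valid at `p_max`) and returns the order
#' minimising `log det(Sigma) + 2 k / T`, where Sigma is the ML
#' residual covariance, k the number of free coefficients and T the
#' number of fitted rows.
#'
#' @param series a `preproc_series`.
#' @param p_max largest candidate order.
#' @return The selected order (integer).
#' @export
select_order_aic <- function(series, p_max = 10) {
  stopifnot(inherits(series, "preproc_series"), p_max >= 1)
  x <- series$x; m <- ncol(x)
  rows <- lag_valid_rows(series$session, p_max)
  if (length(rows) <= p_max * m + 1)
    stop("not enough rows for the requested maximum order", call. = FALSE)
  ld <- lag_design(x, rows, p_max)
  Y <- x[rows, , drop = FALSE]
  T_eff <- length(rows)
  aic <- numeric(p_max)
  for (p in seq_len(p_max)) {
    keep <- seq_len(1 + m * p)
    res <- stats::lm.fit(ld$X[, keep, drop = FALSE], Y)$residuals
    S <- crossprod(res) / T_eff
    k <- m * (m * p + 1)
    aic[p] <- log(det(S)) + 2 * k / T_eff
  }
  which.min(aic)
}

#' Fit a vector autoregression on preprocessed ROI series
#'
#' Per-equation least squares on rows whose full lag window lies within
#' one session.
#'
#' @param series a `preproc_series`.
#' @param order VAR order (>= 1).
#' @return An object of class `sst_var`: list with `order`, `A` (list
#'   of lag coefficient matrices, row = target), `intercept`,
#'   `sigma` (ML residual covariance), `resvar` (per-equation ML
#'   residual variances) and `t_eff`.
#' @export
fit_var <- function(series, order) {
  stopifnot(inherits(series, "preproc_series"), order >= 1)
  x <- series$x; m <- ncol(x)
  rows <- lag_valid_rows(series$session, order)
  if (length(rows) <= m * order + 1)
    stop("not enough usable rows for this order", call. = FALSE)
  ld <- lag_design(x, rows, order)
  qx <- qr(ld$X)
  if (qx$rank < ncol(ld$X)) stop("rank-deficient lag design", call. = FALSE)
  B <- qr.coef(qx, x[rows, , drop = FALSE])
  res <- qr.resid(qx, x[rows, , drop = FALSE])
  A <- lapply(seq_len(order), function(lag) {
    t(B[1 + (lag - 1) * m + seq_len(m), , drop = FALSE])
  })
  sigma <- crossprod(res) / length(rows)
  structure(list(order = order, A = A, intercept = B[1, ],
                 sigma = sigma, resvar = diag(sigma),
                 t_eff = length(rows), roi_names = series$roi_names),
            class = "sst_var")
}

#' @export
print.sst_var <- function(x, ...) {
  cat(sprintf("VAR(%d) fit: %d ROIs, %d usable rows\n",
              x$order, length(x$resvar), x$t_eff))
  invisible(x)
}

# All 12 directed F values at once: one full-model decomposition plus
# one restricted decomposition per source (its lag columns removed).
subject_gca_f <- function(series, order) {
  x <- series$x; m <- ncol(x)
  rows <- lag_valid_rows(series$session, order)
  ld <- lag_design(x, rows, order)
  Y <- x[rows, , drop = FALSE]
  T_eff <- length(rows)
  full_res <- qr.resid(qr(ld$X), Y)
  var_full <- colSums(full_res^2) / T_eff
  F <- matrix(NA_real_, m, m,
              dimnames = list(source = series$roi_names,
                              target = series$roi_names))
  for (src in seq_len(m)) {
    keep <- setdiff(seq_len(ncol(ld$X)), ld$src_cols[[src]])
    res_r <- qr.resid(qr(ld$X[, keep, drop = FALSE]), Y)
    var_r <- colSums(res_r^2) / T_eff
    for (tgt in seq_len(m)) {
      if (tgt == src) next
      F[src, tgt] <- log(var_r[tgt] / var_full[tgt])
    }
  }
  F
}

#' Conditional Geweke influence measure for one connection
#'
#' F(source -> target) is the log ratio of the target-equation residual
#' variance when every lag of the source is omitted (all other ROIs
#' retained — the conditional, multivariate form) to the residual
#' variance of the full model. Non-negative up to sampling noise.
#'
#' @param series a `preproc_series`.
#' @param source,target ROI names or column indices; must differ.
#' @param order VAR order.
#' @return The Geweke F value.
#' @export
geweke_f <- function(series, source, target, order) {
  stopifnot(inherits(series, "preproc_series"))
  rn <- series$roi_names
  if (is.character(source)) source <- match(source, rn)
  if (is.character(target)) target <- match(target, rn)
  if (is.na(source) || is.na(target)) stop("unknown ROI", call. = FALSE)
  if (source == target)
    stop("source and target must differ", call. = FALSE)
  subject_gca_f(series, order)[source, target]
}

#' Phase-randomised surrogate of an ROI series set
#'
#' Per session and per ROI independently, randomises the Fourier phases
#' while keeping the amplitude spectrum, so each surrogate series has
#' the same mean, variance, autocorrelation function and spectrum as
#' the original, but all cross-ROI (and hence any causal) structure is
#' destroyed. Used to build the no-causality null.
#'
#' @param series a `preproc_series`.
#' @param seed optional integer seed.
#' @return A `preproc_series` of the same shape.
#' @export
make_surrogate <- function(series, seed = NULL) {
  stopifnot(inherits(series, "preproc_series"))
  if (!is.null(seed)) set.seed(seed)
  x <- series$x
  for (ss in unique(series$session)) {
    idx <- which(series$session == ss)
    n <- length(idx)
    m <- (n - 1) %/% 2
    for (j in seq_len(ncol(x))) {
      f <- stats::fft(x[idx, j])
      if (m >= 1) {
        k <- 2:(m + 1)
        phi <- stats::runif(m, 0, 2 * pi)
        f[k] <- Mod(f[k]) * exp(1i * phi)
        f[n + 2 - k] <- Conj(f[k])
      }
      x[idx, j] <- Re(stats::fft(f, inverse = TRUE)) / n
    }
  }
  structure(list(x = x, session = series$session,
                 roi_names = series$roi_names),
            class = "preproc_series")
}

# Directed connection labels for m ROIs (source != target), in a fixed
# source-major order.
connection_labels <- function(roi_names) {
  g <- expand.grid(target = roi_names, source = roi_names,
                   stringsAsFactors = FALSE)[, c("source", "target")]
  g <- g[g$source != g$target, ]
  rownames(g) <- NULL
  g
}

# Flatten an F matrix into the connection-label order.
flatten_f <- function(F, conns) {
  mapply(function(s, t) F[s, t], conns$source, conns$target)
}

#' Permutation null of group-mean Geweke F
#'
#' For each permutation, draws one phase-randomised surrogate per
#' subject, computes every directed F, and records the group mean per
#' connection. The group-level critical value is the 95th percentile of
#' this null; per-subject nulls are kept for subject-level decisions.
#'
#' @param cohort_series list of `preproc_series`, one per subject.
#' @param orders integer vector of per-subject VAR orders.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @return List with `null_group` (n_perm x connections matrix),
#'   `null_subject` (n_perm x connections x subjects array) and
#'   `connections`.
#' @export
group_null_distribution <- function(cohort_series, orders, n_perm = 1000,
                                    seed = NULL) {
  stopifnot(length(cohort_series) >= 1,
            length(orders) == length(cohort_series))
  if (!is.null(seed)) set.seed(seed)
  conns <- connection_labels(cohort_series[[1]]$roi_names)
  S <- length(cohort_series)
  nc <- nrow(conns)
  null_subject <- array(NA_real_, c(n_perm, nc, S))
  for (perm in seq_len(n_perm)) {
    for (s in seq_len(S)) {
      surr <- make_surrogate(cohort_series[[s]])
      null_subject[perm, , s] <-
        flatten_f(subject_gca_f(surr, orders[s]), conns)
    }
  }
  null_group <- apply(null_subject, c(1, 2), mean)
  list(null_group = null_group, null_subject = null_subject,
       connections = conns)
}

#' Group-level multivariate Granger causality analysis
#'
#' Full pipeline over one group of subjects: per-subject VAR order by
#' AIC, observed conditional Geweke F for all directed connections,
#' permutation null of the group-mean F from phase-randomised
#' surrogates, Benjamini-Hochberg FDR across connections, and
#' significance flags (group mean above the permutation critical value
#' and FDR-adjusted permutation p below `q`). Subject-level
#' significance compares each subject's F with the 95th percentile of
#' that subject's own surrogate null.
#'
#' @param cohort_series list of per-subject series: `preproc_series`,
#'   `sst_roi_series`, or lists of session matrices (preprocessed as
#'   needed).
#' @param p_max largest candidate VAR order.
#' @param n_perm number of permutations.
#' @param q FDR level.
#' @param seed integer seed.
#' @param orders optional fixed per-subject orders (skips AIC).
#' @param check_stationarity run an ADF test per ROI and warn on
#'   failures.
#' @return An object of class `sst_gca`: list with `connections` (data
#'   frame: `source`, `target`, `group_mean_f`, `f_critical`, `p_perm`,
#'   `p_fdr`, `significant`, `n_subj_significant`), `subject_f`
#'   (subjects x connections), `subject_significant`, `orders`,
#'   `n_perm`, `q`.
#' @export
group_gca <- function(cohort_series, p_max = 10, n_perm = 1000, q = 0.05,
                      seed = NULL, orders = NULL,
                      check_stationarity = FALSE) {
  cohort_series <- lapply(cohort_series, preprocess_series)
  S <- length(cohort_series)
  if (S < 1) stop("empty cohort", call. = FALSE)
  if (n_perm < 100)
    warning("fewer than 100 permutations: null quantiles are coarse",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (check_stationarity) {
    for (s in seq_len(S)) {
      for (j in seq_len(ncol(cohort_series[[s]]$x))) {
        a <- adf_test(cohort_series[[s]]$x[, j])
        if (!a$reject_unit_root)
          warning(sprintf("subject %d ROI %d: unit root not rejected", s, j),
                  call. = FALSE)
      }
    }
  }
  if (is.null(orders))
    orders <- vapply(cohort_series, select_order_aic, integer(1),
                     p_max = p_max)
  conns <- connection_labels(cohort_series[[1]]$roi_names)
  nc <- nrow(conns)
  subject_f <- t(vapply(seq_len(S), function(s)
    flatten_f(subject_gca_f(cohort_series[[s]], orders[s]), conns),
    numeric(nc)))
  obs_group <- colMeans(subject_f)

  null <- group_null_distribution(cohort_series, orders, n_perm)
  f_critical <- apply(null$null_group, 2, stats::quantile, probs = 0.95)
  p_perm <- vapply(seq_len(nc), function(j)
    (1 + sum(null$null_group[, j] >= obs_group[j])) / (n_perm + 1),
    numeric(1))
  p_fdr <- stats::p.adjust(p_perm, method = "BH")
  significant <- obs_group > f_critical & p_fdr < q

  subj_crit <- apply(null$null_subject, c(2, 3), stats::quantile,
                     probs = 0.95)                       # connections x subjects
  subject_significant <- subject_f > t(subj_crit)
  res <- data.frame(conns,
                    group_mean_f = obs_group,
                    f_critical = f_critical,
                    p_perm = p_perm, p_fdr = p_fdr,
                    significant = significant,
                    n_subj_significant = colSums(subject_significant),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(connections = res, subject_f = subject_f,
                 subject_significant = subject_significant,
                 orders = orders, n_perm = n_perm, q = q),
            class = "sst_gca")
}

#' @export
print.sst_gca <- function(x, digits = 3, ...) {
  cat(sprintf("Group GCA: %d subjects, %d permutations, FDR q = %g\n",
              nrow(x$subject_f), x$n_perm, x$q))
  df <- x$connections
  df$group_mean_f <- signif(df$group_mean_f, digits)
  df$f_critical <- signif(df$f_critical, digits)
  df$p_perm <- signif(df$p_perm, digits)
  df$p_fdr <- signif(df$p_fdr, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-connection subject counts
#'
#' Number of subjects showing a significant connection at the
#' subject level, per directed connection; the counts feed the
#' one-tailed Fisher comparison between groups.
#'
#' @param gca an `sst_gca`.
#' @return Named integer vector (`"source->target"`).
#' @export
subject_connection_counts <- function(gca) {
  stopifnot(inherits(gca, "sst_gca"))
  stats::setNames(gca$connections$n_subj_significant,
                  paste0(gca$connections$source, "->",
                         gca$connections$target))
}

#' Compare per-connection subject counts between two groups
#'
#' One-tailed Fisher's exact test (direction of the larger observed
#' proportion) on the number of subjects with a significant connection
#' in each group, per directed connection.
#'
#' @param gca1,gca2 `sst_gca` results for the two groups.
#' @return Data frame with counts, group sizes and the one-tailed p per
#'   connection.
#' @export
connection_count_comparison <- function(gca1, gca2) {
  c1 <- gca1$connections; c2 <- gca2$connections
  stopifnot(identical(c1$source, c2$source),
            identical(c1$target, c2$target))
  n1 <- nrow(gca1$subject_f); n2 <- nrow(gca2$subject_f)
  p <- mapply(fisher_exact_one_tailed,
              c1$n_subj_significant, n1, c2$n_subj_significant, n2)
  data.frame(source = c1$source, target = c1$target,
             k1 = c1$n_subj_significant, n1 = n1,
             k2 = c2$n_subj_significant, n2 = n2,
             p_one_tailed = p, stringsAsFactors = FALSE)
}
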
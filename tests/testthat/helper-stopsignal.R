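# Shared fixtures: small task configurations and quick subject factories.

small_task <- function(n_sessions = 1L, trials = 80L)
  task_config(n_sessions = n_sessions, trials_per_session = trials)

quick_subject <- function(group = "SEQ", seed = 1L, task = task_config(), ...)
  simulate_subject(subject_profile(group, ...), task = task, seed = seed)

# A stable VAR(1) series set with known coefficients, for recovery tests.
make_var1_series <- function(A, n = 1000L, sd = 1, seed = 1L,
                             sessions = 1L) {
  set.seed(seed)
  m <- ncol(A)
  out <- lapply(seq_len(sessions), function(s) {
    burn <- 50L
    z <- matrix(0, n + burn, m)
    e <- matrix(stats::rnorm((n + burn) * m, 0, sd), ncol = m)
    for (t in 2:(n + burn)) z[t, ] <- A %*% z[t - 1, ] + e[t, ]
    z[burn + seq_len(n), , drop = FALSE]
  })
  preprocess_series(out)
}
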
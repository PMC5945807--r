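#' @title Dynamic Bayesian model of stop-signal expectation
#' @description Belief over the latent stop-signal rate r is maintained
#'   on a discrete grid. Before each trial the predictive distribution
#'   mixes the previous posterior (weight alpha) with the generic Beta
#'   prior (weight 1 - alpha); the trial-wise stop expectation P(Stop)
#'   is the mean of that predictive distribution. After the trial the
#'   belief is updated by Bayes' rule with the Bernoulli likelihood of
#'   the observed category (stop = 1, go = 0).
#' @name bayes-observer
NULL

# Internal constructor: a belief grid is a support vector and a
# normalised mass vector of the same length.
belief_grid <- function(support, mass) {
  s <- sum(mass)
  if (!is.finite(s) || s <= 0)
    stop("belief mass is degenerate (non-positive total)", call. = FALSE)
  structure(list(support = support, mass = mass / s), class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("Belief grid: %d points, mean %.4f\n",
              length(x$support), grid_mean(x)))
  invisible(x)
}

#' Mean of a belief grid
#' @param grid a `belief_grid`.
#' @return The expected stop-signal rate under the belief.
#' @export
grid_mean <- function(grid) sum(grid$support * grid$mass)

#' Discretized Beta prior over the stop-signal rate
#'
#' Builds the generic prior Beta(pm * scale, (1 - pm) * scale) on a
#' regular midpoint grid in (0, 1); endpoints are excluded so the
#' Bernoulli likelihood never annihilates the belief.
#'
#' @param params an [observer_params()].
#' @return A `belief_grid`.
#' @examples
#' g <- init_prior(observer_params(pm = 0.25, scale = 4))
#' grid_mean(g)  # ~0.25
#' @export
init_prior <- function(params) {
  n <- params$grid_size
  support <- (seq_len(n) - 0.5) / n
  dens <- stats::dbeta(support, params$pm * params$scale,
                       (1 - params$pm) * params$scale)
  belief_grid(support, dens)
}

#' One predictive (prior-mixing) step
#'
#' Returns the predictive belief for the next trial:
#' `alpha * posterior + (1 - alpha) * prior`, renormalised.
#'
#' @param posterior a `belief_grid`, the posterior after the last trial.
#' @param params an [observer_params()].
#' @param prior optional precomputed [init_prior()] grid (saves
#'   recomputation in long sequences).
#' @return A `belief_grid`.
#' @export
predictive_step <- function(posterior, params, prior = NULL) {
  if (is.null(prior)) prior <- init_prior(params)
  belief_grid(posterior$support,
              params$alpha * posterior$mass + (1 - params$alpha) * prior$mass)
}

#' Bayes update of the belief with one trial outcome
#'
#' Reweights the predictive belief by the Bernoulli likelihood
#' r^s * (1 - r)^(1 - s) of the observed trial category.
#'
#' @param predictive a `belief_grid`.
#' @param stop_observed 1 for a stop trial, 0 for a go trial.
#' @return A `belief_grid`.
#' @export
posterior_update <- function(predictive, stop_observed) {
  if (!stop_observed %in% c(0, 1))
    stop("stop_observed must be 0 or 1", call. = FALSE)
  lik <- if (stop_observed == 1) predictive$support else 1 - predictive$support
  belief_grid(predictive$support, predictive$mass * lik)
}

#' Trial-wise P(Stop) for an outcome sequence
#'
#' Runs the observer over a sequence of trial categories and returns the
#' pre-trial stop expectation for every trial: element k is the mean of
#' the predictive distribution given trials 1..k-1, so element 1 equals
#' the prior mean `pm`.
#'
#' @param outcomes integer vector of trial categories (stop = 1,
#'   go = 0).
#' @param params an [observer_params()].
#' @return Numeric vector of probabilities, same length as `outcomes`.
#' @examples
#' pstop_sequence(c(0, 1, 0), observer_params(alpha = 1, pm = 0.5, scale = 2))
#' @export
pstop_sequence <- function(outcomes, params = observer_params()) {
  n <- length(outcomes)
  if (n == 0L) return(numeric(0))
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be coded stop = 1, go = 0", call. = FALSE)
  prior <- init_prior(params)
  support <- prior$support
  prior_mass <- prior$mass
  post <- prior_mass           # "posterior" before any data is the prior
  alpha <- params$alpha
  out <- numeric(n)
  for (k in seq_len(n)) {
    pred <- if (k == 1L) prior_mass else alpha * post + (1 - alpha) * prior_mass
    pred <- pred / sum(pred)
    out[k] <- sum(support * pred)
    lik <- if (outcomes[k] == 1) support else 1 - support
    post <- pred * lik
    post <- post / sum(post)
  }
  out
}

#' Causal exponential-filter rate estimate
#'
#' A linear, causal, exponentially weighted running estimate of the
#' stop-trial rate, anchored at a prior pseudo-observation. It serves
#' as the independent reference for the observer: the Bayesian
#' predictive mean is essentially an exponential filter over past
#' outcomes.
#'
#' Element k estimates the rate before trial k:
#' \deqn{\hat p_k = \frac{d^{k-1} p_0 + \sum_{j<k} d^{k-1-j} s_j}
#'                      {d^{k-1} + \sum_{j<k} d^{k-1-j}}}
#' with decay d and anchor p0. As d tends to 1 this approaches the
#' cumulative mean.
#'
#' @param outcomes integer vector (stop = 1, go = 0).
#' @param decay forgetting factor in (0, 1\].
#' @param floor_mean prior anchor in (0, 1).
#' @return Numeric vector of rate estimates, same length as `outcomes`.
#' @export
exp_filter_estimate <- function(outcomes, decay, floor_mean = 0.25) {
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]", call. = FALSE)
  n <- length(outcomes)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  num <- floor_mean
  den <- 1
  out[1] <- floor_mean
  for (k in seq_len(n)[-1]) {
    num <- decay * num + outcomes[k - 1]
    den <- decay * den + 1
    out[k] <- num / den
  }
  out
}

#' Best-fit exponential-filter decay for an observer
#'
#' Grid-searches the decay of [exp_filter_estimate()] maximising the
#' Pearson correlation with the observer's P(Stop) sequence.
#'
#' @param outcomes integer vector (stop = 1, go = 0).
#' @param params an [observer_params()].
#' @param decays candidate decay values.
#' @return List with `decay`, `r` (correlation at the optimum) and the
#'   fitted `estimate` sequence.
#' @export
fit_exp_filter <- function(outcomes, params = observer_params(),
                           decays = seq(0.50, 0.999, by = 0.001)) {
  p <- pstop_sequence(outcomes, params)
  best <- list(decay = NA_real_, r = -Inf, estimate = NULL)
  for (d in decays) {
    e <- exp_filter_estimate(outcomes, d, params$pm)
    r <- suppressWarnings(stats::cor(p, e))
    if (is.finite(r) && r > best$r) best <- list(decay = d, r = r, estimate = e)
  }
  best
}

#' Append a P(Stop) column to a trial table
#'
#' Recomputes the analysis observer's trial-wise stop expectation from
#' the outcome sequence of a trial table (as written by the cohort
#' writers) and returns the table with a `pstop` column.
#'
#' @param trials data frame with columns `type` (`"go"`/`"stop"`) in
#'   presentation order.
#' @param params an [observer_params()].
#' @return The trial table with a `pstop` column.
#' @export
add_pstop <- function(trials, params = observer_params()) {
  s <- as.integer(trials$type == "stop")
  trials$pstop <- pstop_sequence(s, params)
  trials
}
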
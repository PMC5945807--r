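---
title: "Models and methods behind stopsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic test bed does and does not
establish about real data.

## The task and the race model

In the stop-signal task a subject responds to a frequent go signal and
must occasionally cancel the response when a stop signal follows after
a short delay (the SSD). The simulator presents sessions of randomly
intermixed trials (`task_config()`): stop trials are independent
Bernoulli draws at `stop_fraction` (default 0.25), the fore-period
between trial onset and go signal is uniform on 1–5 s, responses must
land within a 1 s window, and the SSD follows a one-up/one-down
staircase in 67 ms steps from 200 ms, clamped to `[0, response_window]`
(the stop signal cannot precede the go signal nor outlive the response
window; the bounds are a package choice, as the procedure itself does
not state any).

A subject (`subject_profile()`) is a race between a go process and a
stop process of fixed latency `ssrt_true`. The go finish time is

```
T_go = rt_base + beta_pstop * P(Stop) + beta_fp * (FP - mean FP) + noise
```

with Gaussian noise. A Gaussian is the simplest law sufficient for the
statistics tested here; real RT distributions are right-skewed, which
matters for tail-sensitive quantities but not for the medians,
correlations and staircase behaviour the package measures.
Fore-periods enter mean-centred so `rt_base` is readable as the mean
go-success RT of an average trial. On stop trials a response is
emitted iff `T_go < SSD + ssrt_true`. Because the staircase moves the
SSD one step up after each successful stop and one step down after
each failure, it settles where stopping succeeds half the time, for
any continuous RT distribution.

## The Bayesian observer

The observer (`observer_params()`, `pstop_sequence()`) believes the
stop-signal rate `r` persists between trials with probability `alpha`
and is otherwise re-drawn from a Beta prior with mean `pm` and
concentration `scale` — the unique mean/concentration reading of a
"prior mean and shape parameter" pair. Beliefs live on a regular grid
of 1,000 midpoints in (0, 1); endpoints are excluded so the Bernoulli
likelihood can never annihilate the belief, and the discretisation
error of any posterior mean is bounded by the bin width. P(Stop) is
defined *pre-trial*: it is the mean of the predictive distribution
before the trial's outcome is seen, so the first element of every
sequence equals `pm`.

Defaults are `alpha = 0.8`, `pm = 0.25`, `scale = 10`. The analysis
this package reproduces does not report the numeric values it used, nor
whether they were fitted per subject, so the package treats them as
inputs: `pm` matches the task's true stop fraction, `scale = 10` is a
moderately confident prior, and `alpha = 0.8` gives the observer a
memory of roughly five trials. No fitting of the three parameters to RT
data is provided, deliberately.

Two independent oracles pin the implementation down in the tests: with
`alpha = 1` the grid must track the conjugate Beta–Bernoulli posterior
mean to within two bin widths over 1,000 trials, and with any `alpha`
the sequence must correlate at r ≥ 0.99 with a best-fit causal
exponential filter (`exp_filter_estimate()`), which is what the mixture
update amounts to.

Under these defaults the trial-wise P(Stop) fluctuates with a standard
deviation of only about 0.04. That number drives the calibration of the
generator: for a sequential effect to be *detectable* within a subject
(~290 go-success trials), the RT slope on P(Stop) must be large enough
that `beta_pstop × 0.04` is a measurable fraction of the ~120 ms RT
noise. The default SEQ slope of 0.8 s per unit P(Stop) gives
within-subject r ≈ 0.25 and >90% detection power; a slope of ~0.3 s
would be detected barely half the time.

## Behavioural metrics

`critical_ssd()` implements the mid-run estimate: the stop-trial SSD
series is split into maximal monotone runs, a direction reversal closes
a run *and* opens the next at the same value (shared endpoint), ties
extend the current run, and the estimate is the mean of the medians of
every second run (the 2nd, 4th, …). The underlying procedure does not
pin the endpoint or parity conventions; the package states one and uses
it consistently, and validates the estimator against a maximum
likelihood logistic fit of the 50% point, which it tracks within 20 ms
on 400-trial staircases. SSRT is the median go RT minus the critical
SSD, which may come out negative on pathological series (flagged with a
warning rather than an error).

Classification: a subject is SEQ when the P(Stop)–goRT Pearson
correlation has two-tailed p < 0.05 *and* positive sign. The source
analysis states only "p < 0.05"; positivity is implied by the direction
of the effect it describes, and the two-tailed reading is the
conservative one.

Group tables use pooled-variance t tests: recomputing the published
group comparison from its summary moments (616 ± 123, n = 81 vs
675 ± 132, n = 35) gives t = −2.319, matching the printed value to the
rounding of the inputs, while the unequal-variance form does not.
One-tailed Fisher exact tests on subject counts take their direction
from the larger observed proportion, which is the only direction
recoverable from the reported values.

## The ROI GLM

Designs are built at a microtime resolution of TR/16 and sampled at
volume midpoints. Each outcome condition (GS, GE, SS, SE) contributes
an onset regressor convolved with the canonical double-gamma HRF (peak
6 s, undershoot 16 s, unit dispersions, ratio 6 — the conventional
values; the model is named but not parameterised in the source), its
temporal derivative, and parametric modulators in declared order,
mean-centred per session before convolution (the standard convention
that keeps the unmodulated regressor interpretable). The F1 variant
puts P(Stop) before FP, F2 the reverse, both locked to trial onsets;
the G variant locks to go-signal onsets with unsigned prediction error
and RT as modulators. Modulators are serially orthogonalised within
condition — each column residualised against the onset regressor and
all earlier modulators — so later modulators only receive variance the
earlier ones cannot claim. Orthogonalisation never changes the fitted
signal, only the attribution of shared variance, and with orthogonal
columns the order is provably irrelevant; the tests verify both.

Low-frequency drift is absorbed by a per-session discrete cosine basis
up to a 1/128 Hz cutoff (9 components for a 590 s session) plus a
constant. A finite cosine set attenuates rather than annihilates
drifts whose frequency falls within about one basis step of the
cutoff; drifts with periods of 400 s and longer are removed to below 1%
residual power, which is what the tests assert. Serial autocorrelation
is handled by estimating the lag-1 coefficient from OLS residuals
(within sessions), exact AR(1) prewhitening of both sides, and a
refit.

Motion regressors are accepted as nuisance columns in principle but are
not simulated; spatial preprocessing, voxelwise inference and anatomy
are entirely out of scope — the GLM operates on ROI-average series
only.

## Granger causality

Per session, each ROI series is linearly detrended and z-scored, then
sessions are concatenated with recorded boundaries; every model fit
uses only rows whose full lag window lies inside one session, so
results are invariant to session order. The VAR order is chosen per
subject by AIC (`log det Σ + 2k/T` on a common row set, `p_max = 10`
by default); stationarity can be checked per ROI with a hand-rolled
augmented Dickey–Fuller test (lag 1 by default — the series are short —
with the standard 5% critical values for the constant case). A failed
ADF check warns and continues, since the source analysis reports
confirmation, not remediation. Plain AIC over-selects the order in
roughly 5% of realisations; this is a known property of the criterion,
and an over-selected order leaves the influence measure asymptotically
unchanged.

Directed influence is the conditional Geweke measure: for source →
target, F = ln(σ²_restricted/σ²_full), where the restricted target
equation omits every lag of the source but keeps all other ROIs. The
verbal definition in the source is ambiguous; this is the standard
reading of the measure it cites, and the tests check it against the
closed form on a planted lag-1 coupling (F = ln 1.25 for coefficient
0.5 on unit-variance inputs).

Significance uses surrogate permutation nulls: phases of each session
and ROI are randomised independently in the Fourier domain, preserving
each series' mean, variance, autocorrelation and spectrum exactly while
destroying all cross-series structure. Per permutation, one surrogate
per subject yields an F per connection; the group-level critical value
is the 95th percentile of the null of *group means* (1,000 permutations
by default; the source states neither the count nor the percentile, nor
whether its null pooled subjects — the group-mean null is the reading
consistent with comparing a group-mean F against a critical value).
Connections are flagged when the observed group mean exceeds the
critical value and the Benjamini–Hochberg-adjusted permutation p falls
below q = 0.05 across the 12 directed connections. Subject-level
significance compares each subject's F with the 95th percentile of that
subject's own surrogate null, and those counts feed the one-tailed
Fisher group comparison.

One property of this decision rule deserves emphasis. FDR controls the
expected *proportion* of false flags among discoveries, not the chance
of any false flag. With four genuine connections discovered, the
step-up threshold admits each null connection with probability ≈ 0.02,
so about one run in five carries a single extra flag even though the
per-connection false-flag rate (≈ 0.025) and the sensitivity (1.0 in
our measurements) are excellent. Exact recovery of a planted
connection *set* in ≥ 90% of runs is therefore not achievable under
this rule — not a defect of the implementation but the arithmetic of
FDR under partial alternatives; a familywise-error rule would trade
those extras for misses.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws subject profiles from truncated Gaussians
calibrated so the default cohort approximates the behavioural profile
of the study population it models: 81 SEQ subjects (median goRT
≈ 616 ms, SSRT ≈ 207 ms) and 35 nSEQ subjects (675 ms, 241 ms), stop
success ≈ 51%, and a fore-period effect of r ≈ −0.16 in both groups
with no group difference. The SEQ/nSEQ labels are generative; observed
classification disagrees for ~5% of subjects, exactly as a
threshold-based classification of noisy correlations must.

`simulate_roi_bold()` produces four construct ROIs (stop-signal
anticipation, motor preparation, RT slowing, RT speeding). Each
carries an HRF-convolved event response scaled by its modulator
amplitude — the slowing and speeding ROIs load on go RT with opposite
signs — plus VAR(1) noise whose lag-1 coupling matrix plants the
directed structure of the chosen preset (`SEQ_fig4`: P(Stop) ↔ FP,
P(Stop) → slowing, slowing → speeding; `nSEQ_fig4`: FP → P(Stop),
P(Stop) → slowing, FP → speeding, speeding → slowing; coupling 0.3,
self-coupling 0.2, unit innovations; stability enforced at
construction). Planting connectivity in the noise channel rather than
in the event amplitudes keeps the GLM effects and the connectivity
separable and independently testable.

What passing tests show: the estimators recover what the generator
planted — staircase convergence, SSRT within 15%, GLM amplitudes,
directed connection sets — under Gaussian RTs, exact HRFs, linear
BOLD, and stationary VAR noise. What they cannot show: robustness to
skewed RTs, HRF mismatch, motion and physiological artifacts,
non-stationarity, or hemodynamic confounds of Granger causality on
BOLD-level series (no deconvolution is attempted, matching the source
analysis). Conclusions about real data inherit those caveats.

## Problem sizes and runtime choices

The test suite keeps simulation sizes at the smallest scales that still
pin each property down: staircase convergence uses one 20,000-trial
subject, calibration checks use the full default cohort (116 subjects
of 400 trials), SSRT recovery uses 200 subjects, GLM recovery uses
25–40 noise replicates, and the GCA recovery checks use cohorts of 6
subjects with 150–200 permutations and 3–5 replicate cohorts per
preset. The pipeline defaults (`n_perm = 200`, 12 imaging subjects per
group) are likewise sized for interactive use; for publication-grade
nulls raise `n_perm` to 1,000.
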
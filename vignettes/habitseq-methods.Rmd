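---
title: "Models and methods behind habitseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind habitseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

habitseq analyses per-trial keystroke logs from month-long, app-based motor
sequence training in which participants (e.g. healthy volunteers and
patients with obsessive-compulsive disorder) practice two six-press finger
sequences daily, one under a continuous reward schedule (a score shown on
every correct trial) and one under a variable schedule (score shown on 37%
of trials), with all score feedback removed from a configurable extinction
day (day 21 by default). This vignette documents the models the package
fits, the estimators and numerical choices behind them, and what the
synthetic-data generator does and does not emulate.

## The trial-log data model

A trial log has one row per app trial: participant, group, schedule,
session (practice) id and wall-clock start, study day, outcome, six
key-press timestamps on a within-trial clock (correct trials only), and the
score shown (absent when no feedback was displayed). Timestamps are
seconds; wall-clock times are ISO-8601 UTC. Within-trial press clocks are
deliberately decoupled from wall-clock session starts: the former carry the
kinematics, the latter the diurnal information.

`build_trial_series()` orders a participant's trials chronologically across
sessions and keeps correct trials only; the correct-trial counter *n* is
the x-axis of every learning analysis, so error trials never dilute it.
A *practice* is a session of 20 correct trials; `count_practices()`
defaults to `floor(correct trials / 20)` per schedule (summed over
schedules) because real exports do not always carry an explicit practice
boundary, with a session-id-based count available when they do.

## Learning and automaticity models

Movement time of a correct trial is the span of its six presses,
`MT = t6 - t1`. Learning is modelled per participant and schedule as a
single exponential decay over correct trials,

    MT(n) = MT0 + MTL * exp(-n / nr),

with asymptote `MT0` (s), amount of learning `MTL` (s), and learning rate
`nr` (trials). Automaticity is quantified by the inter-keystroke-interval
(IKI) consistency index, the sum of absolute differences between the five
IKIs of consecutive correct trials,

    C(n) = sum_k |t[k, n+1] - t[k, n]|,

which falls as the timing pattern becomes reproducible; its decline is
fitted with the same family, `C(n) = C0 + CL * exp(-n / nC)`. We index the
consistency of the pair `(n, n+1)` at the earlier trial `n`; any fixed
convention works, and this one keeps the series aligned with the trial on
which the pattern could first have been reproduced.

### Smoothing

Raw series are damped with a trailing (causal) moving average of 20 trials
before fitting; the first `k < 20` points average the `k` observations
available, so the series keeps its length and uses no lookahead. A trailing
window has one analytically convenient property: wherever the window is
full, the average of `a + b*exp(-n/r)` is again exponential with the same
rate and a known amplitude gain `g = mean(exp((0:19)/r))`. `fit_participant()`
therefore fits on the full-window region (`n >= 20`) and divides the fitted
amplitude by `g` evaluated at the fitted rate, which removes both the
run-in distortion of the shrinking windows and the systematic amplitude
inflation the smoother would otherwise cause (about 7% at `r = 142`).

### Fitting

`fit_exp_decay()` uses bounded Levenberg-Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with a deterministic multi-start over candidate rates
{25, 50, 100, 200, 400, 800} plus a data-driven initialisation (asymptote
from the last 50 smoothed points, amplitude from the head-tail difference).
Bounds: asymptote in `(0, max(y)]`, amplitude in `[0, 10*range(y)]`, rate
in `[1, 3*n_max]`. Candidates are ranked by SSE, ties broken by the lower
rate, so the result is independent of the order of the starts. Series are
truncated at a consolidated maximum of `n_max = 1200` correct trials; a
participant with fewer trials is fitted on all available points (the cap is
read as a cap, not an extrapolation target). At least 30 points (ten per
free parameter) are required. A constant series short-circuits to the exact
degenerate solution (asymptote = the constant, amplitude 0, converged).
Convergence tolerances are tightened (`ftol = ptol = 1e-13`) so noiseless
recovery is accurate to better than one part in 10^6.

## Reward sensitivity

The reward change at trial *n* is `dR(n) = R(n) - R(n-1)`; it conditions
the behavioural change into the following trial. The movement-time change
is normalized by its baseline,

    dMT(n+1) = (MT(n+1) - MT(n)) / MT(n),

and the analogous normalized IKI-consistency change is
`normC = sum_k |(t[k,n+1] - t[k,n]) / t[k,n]|`. Per participant, samples
with a positive / negative `dR` sign are split into four training bins and
each cell is summarised by a Gaussian; the centers and spreads feed a
three-way mixed ANOVA (reward sign and bin within participants, group
between).

Decisions where the procedure was genuinely open:

* **Alignment.** `dR(n)` conditions `dMT(n+1)` — the change *following*
  the reward change.
* **Zero and undefined signs.** `dR = 0` transitions belong to neither
  subsample and are excluded (but counted in diagnostics); a transition is
  undefined when either score of the pair was not displayed, which also
  removes the extinction phase by construction.
* **Session gating.** By default the three trials involved in a transition
  (`n-1`, `n`, `n+1`) must share a session; cross-session carryover of a
  displayed score is not assumed. This is configurable.
* **Binning.** The four bins partition the transitions that actually enter
  the conditional analysis (defined nonzero sign), in chronological order,
  into near-equal runs (sizes differ by at most one, remainder to the
  earliest bins). Binning all correct trials instead would leave the late
  bins empty under extinction, which removes all defined samples from the
  last third of training.
* **Gaussian estimation.** The default estimator is sample moments (mean
  and unbiased SD), which is the maximum-likelihood Gaussian fit; a
  least-squares fit to a Freedman-Diaconis histogram is available as a
  fidelity mode (`method = "histogram"`). Cells with fewer than
  `min_samples = 10` values are flagged unavailable rather than producing
  degenerate spreads.

### Why normalize

With any noisy performance series, conditioning on a reward drop selects
trials whose baseline was unusually slow, so the following raw change
`MT(n+1) - MT(n)` is negative by regression to the mean even without any
behavioural sensitivity. On the scale the raw statistic is computed
(milliseconds of sequence duration), this artifact gap is hundreds of ms
early in training, while the normalized index is adimensional and of order
of the noise coefficient of variation; its residual conditioning bias
shrinks proportionally as the noise shrinks. The package's acceptance
checks measure both gaps on a pure-noise cohort and verify the normalized
index collapses the artifact by far more than the five-fold margin
required.

## Circular statistics of practice timing

Practice start hours are embedded on the circle (`theta = 2*pi*h/24`).
Each participant contributes one angle to the group analysis: the mean
direction of all their session start times, matching a
one-dot-per-participant reading of preferred practice time. Group-level
concentration is tested with the Rayleigh statistic `Z = n*Rbar^2` and the
standard series approximation of its p-value, which reproduces published
cohort-scale magnitudes (p about 5e-4 at `Rbar = 0.47`, n = 33) and holds
its nominal type-I rate to within a percentage point at n = 33. Group
comparisons use the two-sample Watson U^2 rank statistic; its primary
p-value comes from a seeded permutation of group labels (exact under
exchangeability and fully reproducible), with the classical critical-value
bracket reported alongside. Whether participant mean directions should be
weighted by their own resultant lengths is unsettled; the package follows
the unweighted one-angle-per-participant reading.

## Group-level inference

Between-group effects on fitted parameters use the tie-corrected
Kruskal-Wallis H (via `stats::kruskal.test`). The sensitivity summaries use
a standard mixed-design ANOVA decomposition via `stats::aov` with
participant error strata (`Error(subject/(sign*bin))`); no sphericity
correction is applied, and F together with both degrees of freedom are
reported so any correction can be applied downstream. Participants missing
a within-cell are dropped listwise with a message. Paired follow-ups use
the dependent-sample t-test, with zero-variance differences flagged as
degenerate instead of erroring. Families of related hypotheses are
corrected with Benjamini-Hochberg FDR (`stats::p.adjust`), one family per
analysis block.

## The synthetic-data generator

`generate_cohort()` produces a full keystroke log plus the ground truth of
every participant, as a pure function of `(config, seed)`. It emulates:

* **Learning curves.** Per-participant true parameters are drawn
  lognormally around the group medians (`param_sdlog` on the log scale, so
  the group value is the population median); movement time follows the
  exponential backbone times multiplicative lognormal noise
  (`mt_noise_cv`, default 5%).
* **Consistency curves.** IKI rows are constructed so that every row sums
  exactly to that trial's movement time while the realized consistency
  index between consecutive rows equals a target
  `C0 + CL*exp(-n/nC)` (times lognormal noise, `c_noise_cv`). Each step
  solves a one-dimensional piecewise-linear equation for the step size
  along a zero-sum, mean-reverting direction; the mean reversion keeps
  deviations from the base IKI profile bounded, and a positivity guard
  keeps every interval above 5% of its nominal share (when the guard
  binds, which is rare, the realized consistency falls below its target,
  never above).
* **Reward schedules.** Scores are a deterministic, strictly decreasing
  function of movement time (`max(0, round(100/mt))` by default — the real
  app's formula is not public, so analyses of real data must read scores
  from the log rather than recompute them), shown on every pre-extinction
  continuous trial, on 37% of variable trials, and never from the
  extinction day on.
* **Reward coupling.** On a transition whose preceding reward change (from
  displayed scores) had nonzero sign, the next movement time is
  `mt[n] * (1 + delta)` with `delta ~ N(mu_sign, sigma_sign)`, so the
  realized normalized change following a reward increment or decrement is
  an exact draw from the configured conditional Gaussian — the quantity
  the sensitivity analysis estimates. Zero-sign and hidden-score
  transitions reset the chain to the exponential backbone; because score
  quantization makes zero signs frequent, the resets bound the
  multiplicative drift and keep the backbone the approximate marginal
  trend. An all-zero coupling disables the mechanism entirely.
* **Engagement structure.** Sessions of 20 correct trials, a configurable
  number per day; error trials inserted i.i.d. (default rate 0.1, a
  realistic sequence-tapping failure rate) carrying no press times; session
  start hours drawn von Mises around a participant-preferred hour, itself
  drawn von Mises around the group hour (default concentrations derived
  from published mean resultant lengths of 0.47 and 0.58 via the inverse
  of `A1`), and sorted within a day so session counters are chronological.

It does **not** emulate: the app's staged cue-removal practice levels,
within-day fatigue or warm-up, sleep consolidation between days, the
actual app scoring formula, score-magnitude (as opposed to sign) effects,
or any group difference in reward sensitivity. Passing recovery tests on
this generator therefore shows the estimators recover the assumed
generative structure at realistic magnitudes and noise levels — not that
real training data satisfy those assumptions.

### Default magnitudes

Group-level defaults are the published continuous-schedule medians
(HV: `MT0` 1.7 s, `MTL` 3.1 s, `nr` 176 trials; `C0` 287 ms, `CL` 1.4 s,
`nC` 142; OCD: 1.8 s, 3.9 s, 200; 301 ms, 1.9 s, 198; preferred hours
15:00 / 18:00). Between-participant spreads are set from the published
interquartile ranges (IQR/median divided by 1.349 on the log scale),
giving `param_sdlog` of roughly 0.17-0.64 depending on the parameter. The
movement-time floor is 0.3 s (a fast but attainable six-press sequence);
the coupling default `(mu-, sigma-, mu+, sigma+) = (-0.05, 0.02, -0.01,
0.02)` makes speeding after reward drops larger than after increments, the
qualitative pattern the sensitivity analysis targets.

## Problem sizes and reproducibility

The test-suite and acceptance computations run at desk scale, chosen so the
full suite completes in minutes on one CPU: recovery cohorts of 30
participants per group with the full 30-day schedule (1200 correct trials
per schedule); ANOVA power over 200 replicate 6-day studies (enough trials
that every sign-by-bin cell clears the 10-sample floor); 10,000 simulations
for type-I calibration and 1000-2000 for power estimates; 1000 random
instances per brute-force oracle comparison. Every stochastic step takes an
explicit seed, the generator restores the caller's RNG state, and the
pipeline writes byte-identical CSVs for identical `(config, seed)`.

## Known limitations

* Replication power of the Rayleigh test at the cohort-scale effect
  (`Rbar` about 0.47, n = 33) is only ~60% at the p < 0.001 level, because
  the sampling spread of `Rbar` at n = 33 is about 0.10; a single
  published small p at this effect size should not be expected to
  reproduce in most simulated cohorts.
* The mixed ANOVA reports uncorrected F tests; strong sphericity
  violations in real data would need a correction the package does not
  apply by default.
* The exponential-decay rate is weakly identified for participants whose
  true rate approaches the series length; their estimates scatter widely
  (the recovery tests absorb this by comparing group medians).
* The generator's coupling mechanism is a descriptive device that realizes
  the conditional Gaussians the analysis estimates; it is not a process
  model of reward learning, and no reinforcement-learning fit is provided.
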
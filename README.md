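# habitseq

Analysis of app-based motor sequence training: learning curves,
automaticity, reward sensitivity, and practice timing.

## What problem this package addresses

In month-long smartphone training studies, participants practice short
finger-press sequences daily — one sequence under a *continuous* reward
schedule (a performance score shown on every correct trial), one under a
*variable* schedule (score shown on 37% of trials) — with score feedback
removed from a configurable extinction day. Such designs are used in
computational psychiatry to phenotype habit formation, e.g. comparing
healthy volunteers with patients with obsessive-compulsive disorder.
habitseq turns the raw per-trial keystroke logs of such a study into the
quantities that carry the scientific claims, for researchers who need
those analyses reusable and testable:

* **Learning.** Movement time of a correct trial, `MT = t6 − t1`, is
  modelled per participant as `MT(n) = MT0 + MTL·exp(−n/nr)` over the
  correct-trial counter *n* — asymptote `MT0`, amount of learning `MTL`,
  learning rate `nr` (trials), after a 20-trial moving average and capped
  at `n_max = 1200`.
* **Automaticity.** The inter-keystroke-interval consistency index
  `C = Σₖ |t(k, n+1) − t(k, n)|` (sum over the five IKIs of consecutive
  correct trials) declines as timing patterns become reproducible and is
  fitted with the same exponential family `C(n) = C0 + CL·exp(−n/nC)`.
* **Reward sensitivity.** The reward change `ΔR(n) = R(n) − R(n−1)`
  conditions the normalized change that follows,
  `ΔMT(n+1) = (MT(n+1) − MT(n))/MT(n)` (and `normC = Σₖ |Δtₖ/tₖ|`), which
  counteracts regression to the mean; per participant the samples are
  split by reward-change sign and four training bins, each cell summarised
  by a Gaussian (μ, σ), then analysed with a three-way mixed ANOVA.
* **Practice timing.** Preferred practice hours on the 24-hour circle: one
  mean direction per participant, group-level Rayleigh test
  (`Z = n·R̄²`), and the two-sample Watson U² test with a seeded
  permutation p-value.
* **Inference layer.** Kruskal–Wallis H, mixed ANOVA with participant
  error strata, dependent-sample t-tests, Benjamini–Hochberg FDR.
* **Synthetic cohorts.** A generator that emulates all of the above with
  known per-participant ground truth, so every stage is testable without
  the study's raw data.

## Worked example

Simulate a small two-group cohort under the continuous schedule and run
the main analyses:

```r
library(habitseq)

cfg <- generator_config(n_per_group = c(HV = 8L, OCD = 8L),
                        schedules = "continuous")
sim <- generate_cohort(cfg, seed = 42)
sim$dataset
#> <study_dataset> 21329 trials, 16 participants, 19200 correct
#>   groups: HV/OCD | schedules: continuous | extinction day: 21

fits <- fit_cohort(sim$dataset, target = "mt")
round(do.call(rbind, lapply(split(fits, fits$group), function(g)
  c(MT0 = median(g$asymptote), MTL = median(g$amplitude),
    nr = median(g$rate)))), 2)
#>      MT0  MTL     nr
#> HV  1.64 2.76 177.79
#> OCD 1.69 3.85 219.00

kruskal_wallis(fits$amplitude, fits$group, effect = "MTL_group")
#>      effect statistic df1 df2         p p_fdr family note
#> 1 MTL_group  4.411765   1  NA 0.0356919    NA   <NA> <NA>

sens <- summarize_sensitivity(sim$dataset, "delta_mt_norm")
round(tapply(sens$mu[sens$available],
             sens$delta_r_sign[sens$available], mean), 4)
#>   minus    plus
#> -0.0501 -0.0096

ph <- participant_mean_hours(sim$dataset)
rayleigh_test(hours_to_angles(ph$mean_hour[ph$group == "HV"]))
#> <circular_summary> n = 8, Rbar = 0.624, mean direction 12.85 h, Z = 3.119, p = 0.0388
```

Reading the output: the fitted group medians sit near the generator's
group truths (asymptote ≈ 1.7/1.8 s, amount of learning 3.1/3.9 s,
learning rate 176/200 trials — small cohorts wander a little); the
Kruskal–Wallis test already separates the groups on `MTL` at n = 8 + 8;
the conditional Gaussian centers recover the injected coupling (−0.05
after reward drops, −0.01 after increments), i.e. participants speed up
more after a drop in score; and the eight HV participants' preferred
practice hours concentrate (R̄ = 0.62) around early afternoon.

The full pipeline — simulate → fit → sensitivity → circadian → report,
five artifact files plus a provenance manifest — runs from a single
configuration:

```r
run_pipeline(list(seed = 1, out_dir = "habitseq-out",
                  generator = list(n_per_group = c(HV = 10L, OCD = 10L))))
```

Trial logs in the documented CSV/JSON-lines dialect (see
`?write_trial_log`) round-trip losslessly through `read_trial_log()`, so
the same pipeline runs on real exports.

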
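test_that("normalized movement-time change behaves as a relative index", {
  expect_equal(delta_mt_normalized(2.0, 1.5), -0.25)
  expect_equal(delta_mt_normalized(1.3, 1.3), 0)
  # adimensional: seconds and milliseconds agree
  expect_equal(delta_mt_normalized(2.0, 1.5),
               delta_mt_normalized(2000, 1500))
  expect_error(delta_mt_normalized(0, 1), "positive")
})

test_that("normC matches hand sums and an elementwise oracle", {
  expect_identical(norm_c(rep(0.2, 5), rep(0.2, 5)), 0)
  expect_equal(norm_c(rep(0.2, 5), c(0.3, 0.1, 0.2, 0.2, 0.2)), 1.0)
  expect_error(norm_c(c(0, 0.2, 0.2, 0.2, 0.2), rep(0.2, 5)), "positive")
  loop_oracle <- function(a, b) {
    out <- 0
    for (k in 1:5) out <- out + abs((b[k] - a[k]) / a[k])
    out
  }
  set.seed(51)
  for (i in 1:200) {
    a <- runif(5, 0.05, 1)
    b <- runif(5, 0.05, 1)
    expect_equal(norm_c(a, b), loop_oracle(a, b))
    # uniform rescaling of all timestamps leaves it unchanged
    expect_equal(norm_c(3 * a, 3 * b), norm_c(a, b))
  }
})

test_that("reward-change signs cover all cases", {
  expect_identical(delta_r_sign(10, 12), "plus")
  expect_identical(delta_r_sign(12, 10), "minus")
  expect_identical(delta_r_sign(12, 12), "zero")
  expect_identical(delta_r_sign(NA, 12), "undefined")
  expect_identical(delta_r_sign(12, NA), "undefined")
})

test_that("bin partition is contiguous, near-equal, earliest-heavy", {
  b440 <- assign_bins(440, 4)
  expect_identical(as.integer(table(b440)), rep(110L, 4))
  expect_identical(as.integer(table(assign_bins(10, 4))), c(3L, 3L, 2L, 2L))
  expect_error(assign_bins(3, 4), "at least")
  for (n in 4:1000) {
    tb <- table(assign_bins(n, 4))
    expect_identical(sum(tb), as.integer(n))
    expect_lte(max(tb) - min(tb), 1L)
  }
})

test_that("delta samples align the reward change with the following transition", {
  # three correct trials: scores 10, 8, 11; mt 2.0, 1.8, 1.9
  tr <- make_trials(list(press_for_mt(2.0), press_for_mt(1.8),
                         press_for_mt(1.9)),
                    score = c(10, 8, 11))
  s <- build_trial_series(study_dataset(tr), "P1", "continuous")
  samp <- collect_delta_samples(s, n_bins = 1)
  expect_identical(nrow(samp), 2L)
  # first transition has no R(0): undefined
  expect_identical(samp$delta_r_sign[1], "undefined")
  # dR(2) = 8 - 10 < 0 conditions dMT(3) = (1.9 - 1.8)/1.8
  expect_identical(samp$delta_r_sign[2], "minus")
  expect_equal(samp$delta_mt_norm[2], (1.9 - 1.8) / 1.8)
  diag <- attr(samp, "diagnostics")
  expect_identical(unname(diag["minus"]), 1L)
  expect_identical(unname(diag["undefined"]), 1L)
})

test_that("all-equal scores yield no signed samples, only zero diagnostics", {
  tr <- make_trials(rep(list(press_for_mt(2.0)), 5), score = rep(10, 5))
  s <- build_trial_series(study_dataset(tr), "P1", "continuous")
  samp <- collect_delta_samples(s, n_bins = 1)
  expect_identical(sum(samp$delta_r_sign %in% c("plus", "minus")), 0L)
  expect_identical(unname(attr(samp, "diagnostics")["zero"]), 3L)
})

test_that("session boundaries gate the sign by default", {
  tr1 <- make_trials(rep(list(press_for_mt(2.0)), 2), score = c(10, 12),
                     session_id = 1L)
  tr2 <- make_trials(rep(list(press_for_mt(1.9)), 3), score = c(13, 9, 8),
                     session_id = 2L,
                     session_start = "2023-01-01T18:00:00")
  s <- build_trial_series(study_dataset(rbind(tr1, tr2)), "P1", "continuous")
  # transitions: 1->2 needs R(0); 2->3 and 3->4 straddle the session break
  # for part of their trial triplet; 4->5 is fully inside session 2
  gated <- collect_delta_samples(s, n_bins = 1)
  expect_identical(gated$delta_r_sign,
                   c("undefined", "undefined", "undefined", "minus"))
  open <- collect_delta_samples(s, n_bins = 1, within_session_only = FALSE)
  expect_identical(open$delta_r_sign,
                   c("undefined", "plus", "plus", "minus"))
})

test_that("Gaussian cell summaries estimate their sample law", {
  const <- fit_conditional_gaussian(rep(0.04, 25))
  expect_equal(const$mu, 0.04)
  expect_equal(const$sigma, 0)
  expect_identical(const$m, 25L)
  small <- fit_conditional_gaussian(rnorm(5))
  expect_false(small$available)
  set.seed(52)
  x <- rnorm(10000, -0.05, 0.02)
  mom <- fit_conditional_gaussian(x)
  expect_lt(abs(mom$mu + 0.05), 3 * 0.02 / sqrt(10000))
  expect_lt(abs(mom$sigma - 0.02) / 0.02, 0.05)
  hist_fit <- fit_conditional_gaussian(x, method = "histogram")
  expect_lt(abs(hist_fit$mu - mom$mu), 0.02 * 0.02 + 2e-4)
  expect_lt(abs(hist_fit$sigma - mom$sigma) / mom$sigma, 0.02)
})

test_that("cohort summaries recover the injected coupling structure", {
  sim <- small_cohort(seed = 53, n_per_group = c(HV = 6L, OCD = 6L),
                      days = 8L, schedules = "continuous")
  sens <- summarize_sensitivity(sim$dataset, "delta_mt_norm")
  ok <- sens[sens$available, ]
  expect_true(all(c("participant_id", "delta_r_sign", "bin", "mu", "sigma",
                    "m") %in% names(ok)))
  gm <- tapply(ok$mu, ok$delta_r_sign, mean)
  expect_lt(gm[["minus"]], gm[["plus"]])
  expect_lt(abs(gm[["minus"]] - (-0.05)), 0.005)
  expect_lt(abs(gm[["plus"]] - (-0.01)), 0.005)
})

test_that("an under-sampled cell is flagged without harming the others", {
  sim <- small_cohort(seed = 53, n_per_group = c(HV = 6L, OCD = 6L),
                      days = 8L, schedules = "continuous")
  sens <- summarize_sensitivity(sim$dataset, "delta_mt_norm",
                                min_samples = 100000L)
  expect_true(all(!sens$available))
  expect_true(all(is.na(sens$mu)))
  sens2 <- summarize_sensitivity(sim$dataset, "delta_mt_norm")
  expect_gt(mean(sens2$available), 0.9)
})

test_that("normalization suppresses the regression-to-the-mean artifact", {
  # pure noise, no coupling: the raw gap (in ms, the scale sequence
  # duration is analysed on) is large, the
  # normalized gap collapses, and it shrinks further as noise shrinks
  gap <- function(cv, seed) {
    sim <- generate_cohort(generator_config(
      n_per_group = c(HV = 4L), days = 10L, schedules = "continuous",
      mt_noise_cv = cv, error_rate = 0, reward_coupling = coupling_off),
      seed = seed)
    samp <- do.call(rbind, lapply(
      unique(sim$dataset$trials$participant_id),
      function(p) collect_delta_samples(
        build_trial_series(sim$dataset, p, "continuous"))))
    raw_ms <- 1000 * tapply(samp$delta_mt, samp$delta_r_sign, mean)
    nrm <- tapply(samp$delta_mt_norm, samp$delta_r_sign, mean)
    c(raw = abs(raw_ms[["minus"]] - raw_ms[["plus"]]),
      norm = abs(nrm[["minus"]] - nrm[["plus"]]))
  }
  g5 <- gap(0.05, 61)
  expect_gt(g5[["raw"]], 5 * g5[["norm"]])
  g2 <- gap(0.02, 61)
  expect_lt(g2[["norm"]], g5[["norm"]])
})
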
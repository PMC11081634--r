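# Reward sensitivity: normalized trial-to-trial change statistics
# conditioned on the sign of the preceding reward change, binned over
# training, summarised per participant by conditional Gaussians.
#
# The reward change at trial n is dR(n) = R(n) - R(n-1); it conditions the
# behavioral change into trial n+1. Movement-time change is normalized by
# the baseline trial, dMT(n+1) = (MT(n+1) - MT(n)) / MT(n), to counteract
# the regression-to-the-mean artifact that ties a slow trial n to an
# apparently large subsequent improvement. The analogous normalized IKI
# consistency change is normC = sum_k |(t[k,n+1] - t[k,n]) / t[k,n]|.

#' Normalized trial-to-trial movement-time change
#'
#' `(mt_next - mt_n) / mt_n`: the adimensional change relative to the
#' baseline trial.
#'
#' @param mt_n,mt_next movement times (seconds) of trials `n` and `n + 1`;
#'   vectorised.
#' @return adimensional change(s), always > -1 for positive inputs.
#' @export
delta_mt_normalized <- function(mt_n, mt_next) {
  if (any(is.na(mt_n)) || any(mt_n <= 0)) {
    stop("baseline movement time must be positive")
  }
  (mt_next - mt_n) / mt_n
}

#' Normalized trial-to-trial IKI consistency
#'
#' Sum over the 5 inter-keystroke intervals of the absolute relative change
#' from trial `n` to `n + 1`: adimensional, 0 iff the timing pattern is
#' exactly reproduced.
#'
#' @param iki_n,iki_next numeric vectors of 5 inter-keystroke intervals
#'   (seconds); the baseline `iki_n` must be strictly positive.
#' @return adimensional consistency change (>= 0).
#' @export
norm_c <- function(iki_n, iki_next) {
  if (length(iki_n) != 5L || length(iki_next) != 5L) {
    stop("IKI rows must have exactly 5 intervals")
  }
  if (anyNA(iki_n) || any(iki_n <= 0)) {
    stop("baseline IKI intervals must be positive")
  }
  sum(abs((iki_next - iki_n) / iki_n))
}

#' Sign of a trial-to-trial reward change
#'
#' @param score_prev,score_curr scores of trials `n - 1` and `n`; `NA` for
#'   trials without displayed feedback. Vectorised.
#' @return character: "plus", "minus", "zero", or "undefined" when either
#'   score is absent.
#' @export
delta_r_sign <- function(score_prev, score_curr) {
  out <- rep("undefined", length(score_curr))
  ok <- !is.na(score_prev) & !is.na(score_curr)
  d <- score_curr[ok] - score_prev[ok]
  out[ok] <- ifelse(d > 0, "plus", ifelse(d < 0, "minus", "zero"))
  out
}

#' Partition correct sequences into near-equal training bins
#'
#' Contiguous partition of trials `1..n_total_correct` into `n_bins` bins
#' whose sizes differ by at most one, any remainder allocated to the
#' earliest bins.
#'
#' @param n_total_correct total number of correct sequences.
#' @param n_bins number of bins (default 4).
#' @return integer vector of length `n_total_correct` giving the bin
#'   (1-based) of each trial.
#' @export
assign_bins <- function(n_total_correct, n_bins = 4L) {
  n_total_correct <- as.integer(n_total_correct)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_total_correct < n_bins) {
    stop("need at least as many sequences as bins")
  }
  base <- n_total_correct %/% n_bins
  rem <- n_total_correct %% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= rem)
  rep.int(seq_len(n_bins), sizes)
}

#' Collect trial-to-trial change samples of one series
#'
#' One sample per consecutive correct-trial transition `n -> n + 1`, carrying
#' the raw and normalized movement-time change, the normalized IKI
#' consistency, the sign of the reward change at the baseline trial `n`
#' (`dR(n) = R(n) - R(n-1)`), and the training bin. The sign is "undefined"
#' when either score of the reward pair is absent or (by default) when the
#' three trials involved do not share a session. Training bins partition the
#' transitions that enter the conditional analysis — those with a defined
#' nonzero reward-change sign, in chronological order — into `n_bins`
#' near-equal runs, so bin sizes per participant differ by at most one
#' regardless of how feedback (extinction, variable schedule) thins the
#' usable samples; other transitions carry `bin = NA`.
#'
#' @param series a `trial_series`.
#' @param n_bins number of training bins (default 4).
#' @param within_session_only if `TRUE` (default), only transitions whose
#'   trials `n - 1`, `n`, `n + 1` fall in one session yield a defined sign.
#' @return data.frame with columns `n`, `delta_mt` (seconds),
#'   `delta_mt_norm`, `norm_c`, `delta_r_sign`, `bin`; attribute
#'   `"diagnostics"` counts transitions per sign category.
#' @export
collect_delta_samples <- function(series, n_bins = 4L,
                                  within_session_only = TRUE) {
  stopifnot(inherits(series, "trial_series"))
  N <- length(series$mt)
  if (N < 2L) {
    out <- data.frame(n = integer(), delta_mt = numeric(),
                      delta_mt_norm = numeric(), norm_c = numeric(),
                      delta_r_sign = character(), bin = integer())
    attr(out, "diagnostics") <- c(plus = 0L, minus = 0L, zero = 0L,
                                  undefined = 0L)
    return(out)
  }
  idx <- seq_len(N - 1L) # baseline trial n of each transition n -> n+1
  mt_n <- series$mt[idx]
  mt_next <- series$mt[idx + 1L]
  dmt <- mt_next - mt_n
  dmt_norm <- delta_mt_normalized(mt_n, mt_next)
  nc <- rowSums(abs((series$iki[idx + 1L, , drop = FALSE] -
                       series$iki[idx, , drop = FALSE]) /
                      series$iki[idx, , drop = FALSE]))
  sgn <- rep("undefined", N - 1L)
  has_prev <- idx >= 2L
  sgn[has_prev] <- delta_r_sign(series$score[idx[has_prev] - 1L],
                                series$score[idx[has_prev]])
  if (within_session_only) {
    same <- has_prev &
      series$session_id[pmax(idx - 1L, 1L)] == series$session_id[idx] &
      series$session_id[idx] == series$session_id[idx + 1L]
    sgn[!same] <- "undefined"
  }
  bin <- rep(NA_integer_, N - 1L)
  usable <- which(sgn %in% c("plus", "minus"))
  if (length(usable) >= n_bins) {
    bin[usable] <- assign_bins(length(usable), n_bins)
  }
  out <- data.frame(n = idx, delta_mt = dmt, delta_mt_norm = dmt_norm,
                    norm_c = nc, delta_r_sign = sgn, bin = bin)
  attr(out, "diagnostics") <-
    c(plus = sum(sgn == "plus"), minus = sum(sgn == "minus"),
      zero = sum(sgn == "zero"), undefined = sum(sgn == "undefined"))
  out
}

#' Gaussian summary of a change-sample cell
#'
#' Summarises a vector of adimensional change values by the center and
#' spread of a fitted Gaussian. The default estimator is sample moments
#' (mean, unbiased SD); `method = "histogram"` instead least-squares-fits a
#' Gaussian density to a Freedman-Diaconis histogram, for fidelity with
#' histogram-based fitting.
#'
#' @param samples numeric vector of change values.
#' @param min_samples minimum sample count below which the summary is
#'   unavailable (default 10).
#' @param method "moments" or "histogram".
#' @return list with `mu`, `sigma`, `m` (sample count), `available`.
#' @export
fit_conditional_gaussian <- function(samples, min_samples = 10L,
                                     method = c("moments", "histogram")) {
  method <- match.arg(method)
  samples <- samples[!is.na(samples)]
  m <- length(samples)
  if (m < min_samples) {
    return(list(mu = NA_real_, sigma = NA_real_, m = m, available = FALSE))
  }
  if (method == "moments" || length(unique(samples)) < 3L) {
    return(list(mu = mean(samples), sigma = sd(samples), m = m,
                available = TRUE))
  }
  brk <- pretty(range(samples), n = max(grDevices::nclass.FD(samples), 5L))
  h <- graphics::hist(samples, breaks = brk, plot = FALSE)
  xs <- h$mids
  ys <- h$density
  start <- list(mu = mean(samples), sigma = max(sd(samples), 1e-9))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ exp(-(xs - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)),
      start = start,
      lower = c(mu = -Inf, sigma = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu = mean(samples), sigma = sd(samples), m = m,
                available = TRUE))
  }
  cf <- coef(fit)
  list(mu = unname(cf[["mu"]]), sigma = unname(abs(cf[["sigma"]])), m = m,
       available = TRUE)
}

#' Conditional change summaries for a whole dataset
#'
#' For every participant, collects the trial-to-trial change samples of the
#' chosen schedule, splits them by reward-change sign (increment /
#' decrement) and training bin, and fits a Gaussian to each cell. The
#' long-format result feeds directly into [mixed_anova_3way()] with
#' `delta_r_sign` and `bin` as within-participant factors and `group`
#' between participants.
#'
#' @param dataset a `study_dataset`.
#' @param measure "delta_mt_norm" (normalized movement-time change) or
#'   "norm_c" (normalized IKI consistency change).
#' @param schedule reward schedule to analyse (default "continuous").
#' @param n_bins number of training bins (default 4).
#' @param min_samples minimum cell size for an available summary.
#' @param method Gaussian estimator, see [fit_conditional_gaussian()].
#' @param within_session_only see [collect_delta_samples()].
#' @return data.frame with one row per participant x sign x bin: columns
#'   `participant_id`, `group`, `schedule`, `measure`, `delta_r_sign`,
#'   `bin`, `mu`, `sigma`, `m`, `available`.
#' @export
summarize_sensitivity <- function(dataset,
                                  measure = c("delta_mt_norm", "norm_c"),
                                  schedule = "continuous", n_bins = 4L,
                                  min_samples = 10L,
                                  method = c("moments", "histogram"),
                                  within_session_only = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  measure <- match.arg(measure)
  method <- match.arg(method)
  tr <- dataset$trials
  ids <- unique(tr$participant_id[tr$schedule == schedule])
  rows <- list()
  for (pid in ids) {
    series <- build_trial_series(dataset, pid, schedule)
    samp <- collect_delta_samples(series, n_bins = n_bins,
                                  within_session_only = within_session_only)
    for (sgn in c("plus", "minus")) {
      for (b in seq_len(n_bins)) {
        vals <- samp[[measure]][which(samp$delta_r_sign == sgn &
                                        samp$bin == b)]
        fit <- fit_conditional_gaussian(vals, min_samples = min_samples,
                                        method = method)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = series$group, schedule = schedule,
          measure = measure, delta_r_sign = sgn, bin = b,
          mu = fit$mu, sigma = fit$sigma, m = fit$m,
          available = fit$available)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
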
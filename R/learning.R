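# Learning and automaticity: movement time, IKI consistency, moving-average
# smoothing, and per-participant exponential-decay fits.
#
# Learning is quantified by the decline of movement time over correct trials,
#   MT(n) = MT0 + MTL * exp(-n / nr),
# and automaticity by the decline of the trial-to-trial IKI consistency index
#   C(n)  = C0  + CL  * exp(-n / nC),
# where the asymptote is the plateau reached by the end of training, the
# amplitude (MTL / CL) the total improvement, and the rate (nr / nC) the
# trial constant of the decay.

#' Movement time of one correct trial
#'
#' The duration of one sequence execution: time of the last (6th) minus the
#' first key press.
#'
#' @param press_times numeric vector of 6 strictly increasing key-press
#'   timestamps (seconds, within-trial clock).
#' @return movement time in seconds.
#' @export
movement_time <- function(press_times) {
  if (length(press_times) != 6L || anyNA(press_times)) {
    stop("press_times must be 6 non-missing timestamps")
  }
  if (any(diff(press_times) <= 0)) {
    stop("press_times must be strictly increasing")
  }
  press_times[6L] - press_times[1L]
}

#' Trial-to-trial IKI consistency index
#'
#' Sum of absolute differences between the inter-keystroke intervals of two
#' consecutive correct trials. Zero means an exactly reproduced timing
#' pattern; lower values indicate more automatic execution.
#'
#' @param iki_n,iki_next numeric vectors of 5 positive inter-keystroke
#'   intervals (seconds) of trials `n` and `n + 1`.
#' @return consistency index `C` in seconds (>= 0).
#' @export
consistency <- function(iki_n, iki_next) {
  if (length(iki_n) != 5L || length(iki_next) != 5L) {
    stop("IKI rows must have exactly 5 intervals")
  }
  if (anyNA(iki_n) || anyNA(iki_next) || any(iki_n <= 0) ||
      any(iki_next <= 0)) {
    stop("IKI intervals must be positive and non-missing")
  }
  sum(abs(iki_next - iki_n))
}

#' Trailing moving average
#'
#' Causal moving average used to damp outlier trials before curve fitting:
#' element `i` is the mean of the last `min(window, i)` observations, so the
#' output has the same length as the input and no lookahead.
#'
#' @param x numeric vector.
#' @param window window length in trials (default 20).
#' @return smoothed vector, same length as `x`.
#' @export
smooth_series <- function(x, window = 20L) {
  if (!length(x)) stop("cannot smooth an empty series")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be an integer >= 1")
  if (window == 1L) return(as.numeric(x))
  cs <- cumsum(as.numeric(x))
  n <- length(x)
  idx <- seq_len(n)
  lag <- pmax(idx - window, 0L)
  lead_sum <- c(0, cs)[lag + 1L]
  (cs - lead_sum) / pmin(idx, window)
}

.exp_decay <- function(n, asymptote, amplitude, rate) {
  asymptote + amplitude * exp(-n / rate)
}

#' Fit a bounded exponential decay
#'
#' Fits `y(n) = asymptote + amplitude * exp(-n / rate)` by bounded
#' Levenberg-Marquardt nonlinear least squares ([minpack.lm::nlsLM]) with a
#' deterministic multi-start over candidate rates, so the result does not
#' depend on luck of a single initialisation. Candidate solutions are ranked
#' by SSE with ties broken by the lower rate.
#'
#' Bounds: asymptote in (0, max(y)], amplitude in [0, 10 * range(y)],
#' rate in [1, 3 * n_max].
#'
#' @param y response values ordered by trial number.
#' @param n trial numbers (default `seq_along(y)`).
#' @param n_max consolidated maximum trial number; observations beyond it are
#'   discarded before fitting (default 1200).
#' @param rate_grid multi-start candidates for the rate (trials).
#' @param min_points minimum observations required after truncation
#'   (default 30, i.e. ten per free parameter).
#' @return an object of class `exp_decay_fit`: list with `asymptote`,
#'   `amplitude`, `rate`, `rmse`, `n_used`, `converged`, `init_used`.
#' @export
fit_exp_decay <- function(y, n = seq_along(y), n_max = 1200L,
                          rate_grid = c(25, 50, 100, 200, 400, 800),
                          min_points = 30L) {
  stopifnot(length(y) == length(n))
  keep <- !is.na(y) & n <= n_max
  y <- as.numeric(y[keep]); n <- as.numeric(n[keep])
  if (length(y) < min_points) {
    stop(sprintf("insufficient data: %d points after truncation, need >= %d",
                 length(y), min_points))
  }
  yr <- diff(range(y))
  if (yr == 0) {
    # degenerate flat series: exact solution with no decay component
    return(structure(list(asymptote = y[1L], amplitude = 0, rate = 1,
                          rmse = 0, n_used = length(y), converged = TRUE,
                          init_used = c(asymptote = y[1L], amplitude = 0,
                                        rate = 1)),
                     class = "exp_decay_fit"))
  }
  a_init <- mean(tail(y, min(50L, length(y))))
  a_init <- min(max(a_init, 1e-8), max(y))
  b_init <- max(mean(head(y, min(20L, length(y)))) - a_init, 1e-8)
  lower <- c(asymptote = 1e-8, amplitude = 0, rate = 1)
  upper <- c(asymptote = max(y), amplitude = 10 * yr, rate = 3 * n_max)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                     maxiter = 500)
  best <- NULL
  for (r0 in sort(rate_grid)) {
    start <- c(asymptote = a_init, amplitude = min(b_init, upper[["amplitude"]]),
               rate = min(max(r0, 1), 3 * n_max))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ asymptote + amplitude * exp(-n / rate),
        data = data.frame(n = n, y = y),
        start = as.list(start), lower = lower, upper = upper,
        control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    cf <- coef(fit)
    cand <- list(coef = cf, sse = sse,
                 converged = isTRUE(fit$convInfo$isConv) ||
                   is.null(fit$convInfo),
                 init = start)
    if (is.null(best) || cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 &&
         cand$coef[["rate"]] < best$coef[["rate"]])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("exponential-decay fit failed from every start")
  }
  structure(list(asymptote = unname(best$coef[["asymptote"]]),
                 amplitude = unname(best$coef[["amplitude"]]),
                 rate = unname(best$coef[["rate"]]),
                 rmse = sqrt(best$sse / length(y)),
                 n_used = length(y),
                 converged = best$converged,
                 init_used = best$init),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit> asymptote %.4g + amplitude %.4g * exp(-n/%.4g)\n",
    x$asymptote, x$amplitude, x$rate))
  cat(sprintf("  rmse %.4g, n_used %d, converged %s\n",
              x$rmse, x$n_used, x$converged))
  invisible(x)
}

#' @export
predict.exp_decay_fit <- function(object, n, ...) {
  .exp_decay(n, object$asymptote, object$amplitude, object$rate)
}

#' Fit the learning or automaticity profile of one participant
#'
#' Builds the movement-time series `MT(n)` (`target = "mt"`) or the IKI
#' consistency series `C(n)` (`target = "c"`; the consistency of the pair
#' `(n, n + 1)` indexed at the earlier trial `n`), smooths it with a trailing
#' moving average, truncates at `n_max` and fits the exponential decay.
#'
#' A trailing window applied to `a + b * exp(-n/r)` yields, wherever the
#' window is full, `a + b * g * exp(-n/r)` with the known gain
#' `g = mean(exp((0:(window-1))/r))`: the rate is untouched and the
#' amplitude is inflated by `g`. To keep the fitted parameters on the scale
#' of the unsmoothed curve, the fit therefore uses the full-window region
#' (`n >= window`) and divides the fitted amplitude by `g` evaluated at the
#' fitted rate. When the series is too short for that, all smoothed points
#' are used and no gain correction is applied.
#'
#' @param series a `trial_series` from [build_trial_series()].
#' @param target "mt" for movement time, "c" for IKI consistency.
#' @param window moving-average window (default 20 trials).
#' @inheritParams fit_exp_decay
#' @return an `exp_decay_fit`.
#' @export
fit_participant <- function(series, target = c("mt", "c"), window = 20L,
                            n_max = 1200L, ...) {
  stopifnot(inherits(series, "trial_series"))
  target <- match.arg(target)
  if (target == "mt") {
    y <- series$mt
  } else {
    m <- nrow(series$iki)
    if (is.null(m) || m < 2L) stop("need at least 2 correct trials for C(n)")
    y <- rowSums(abs(series$iki[-1L, , drop = FALSE] -
                       series$iki[-m, , drop = FALSE]))
  }
  window <- as.integer(window)
  y_s <- smooth_series(y, window)
  min_points <- 30L
  if (length(y_s) >= window + min_points) {
    idx <- seq.int(window, length(y_s))
    fit <- fit_exp_decay(y_s[idx], n = idx, n_max = n_max, ...)
    gain <- mean(exp((0:(window - 1L)) / fit$rate))
    fit$amplitude <- fit$amplitude / gain
  } else {
    fit <- fit_exp_decay(y_s, n = seq_along(y_s), n_max = n_max, ...)
  }
  fit
}

#' Fit every participant x schedule in a dataset
#'
#' Convenience wrapper running [fit_participant()] over all participant and
#' schedule combinations present in a dataset.
#'
#' @inheritParams fit_participant
#' @param dataset a `study_dataset`.
#' @return data.frame with one row per participant x schedule: columns
#'   `participant_id`, `group`, `schedule`, `target`, `asymptote`,
#'   `amplitude`, `rate`, `rmse`, `n_used`, `converged`.
#' @export
fit_cohort <- function(dataset, target = c("mt", "c"), window = 20L,
                       n_max = 1200L, ...) {
  stopifnot(inherits(dataset, "study_dataset"))
  target <- match.arg(target)
  tr <- dataset$trials
  combos <- unique(tr[, c("participant_id", "group", "schedule")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    series <- build_trial_series(dataset, combos$participant_id[i],
                                 combos$schedule[i])
    fit <- tryCatch(
      fit_participant(series, target, window = window, n_max = n_max, ...),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(participant_id = combos$participant_id[i],
               group = combos$group[i], schedule = combos$schedule[i],
               target = target, asymptote = fit$asymptote,
               amplitude = fit$amplitude, rate = fit$rate, rmse = fit$rmse,
               n_used = fit$n_used, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
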
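# Synthetic keystroke-log generator.
#
# Emulates the statistical structure the analysis modules assume, with known
# per-participant ground truth:
#   * movement time decaying as MT0 + MTL*exp(-n/nr) with multiplicative
#     lognormal noise;
#   * IKI rows constructed so the trial-to-trial consistency index follows
#     C0 + CL*exp(-n/nC) while every row still sums exactly to MT(n);
#   * continuous vs variable (37% shown) reward schedules, extinction of
#     feedback from a configurable study day;
#   * reward-sign-coupled trial-to-trial movement-time adjustments;
#   * per-group von Mises diurnal practice-time distributions;
#   * i.i.d. error trials that never enter the correct-trial counter.

#' Von Mises concentration from a mean resultant length
#'
#' Inverts `A1(kappa) = I1(kappa) / I0(kappa)` with Fisher's standard
#' piecewise approximation, so a diurnal concentration can be specified by
#' the mean resultant length it should produce.
#'
#' @param rbar mean resultant length in \[0, 1).
#' @return concentration `kappa >= 0`.
#' @export
vonmises_kappa <- function(rbar) {
  stopifnot(rbar >= 0, rbar < 1)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to the circular uniform when
#' `kappa` is (numerically) zero.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter (>= 0).
#' @return angles in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (kappa < 1e-9) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3L] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

#' Points awarded for a trial
#'
#' Deterministic score, strictly decreasing in movement time down to a floor
#' of zero: `max(0, round(scale / mt))`.
#'
#' @param mt movement time in seconds (> 0); vectorised.
#' @param scale numerator of the score rule (default 100).
#' @return nonnegative integer score(s).
#' @export
score_function <- function(mt, scale = 100) {
  if (any(is.na(mt)) || any(mt <= 0)) stop("mt must be positive")
  pmax(0, round(scale / mt))
}

#' Configuration of the synthetic cohort generator
#'
#' Returns a validated configuration with defaults describing a month-long
#' two-schedule training study: 30 days, two practices of 20 correct trials
#' per schedule per day, feedback extinction from day 21, scores shown on
#' 37% of variable-schedule trials, and per-group learning / automaticity /
#' diurnal ground truths. Per-participant true parameters are drawn
#' lognormally around the group values (`param_sdlog` on the log scale), so
#' the group value is the population median.
#'
#' @param n_per_group named integer vector of cohort sizes.
#' @param days training days.
#' @param practices_per_day practices per schedule per day.
#' @param trials_per_practice correct trials per practice.
#' @param schedules subset of `c("continuous", "variable")`.
#' @param learning,automaticity per-group named vectors `c(mt0, mtl, nr)` /
#'   `c(c0, cl, nc)`: asymptote (s), amplitude (s) and rate (trials) of the
#'   exponential decays.
#' @param param_sdlog between-participant log-scale spreads per parameter.
#' @param mt_noise_cv coefficient of variation of multiplicative
#'   movement-time noise.
#' @param c_noise_cv coefficient of variation of the consistency target
#'   noise.
#' @param iki_profile base 5-simplex of IKI proportions (positive, sums
#'   to 1).
#' @param reward_coupling named vector `c(mu_minus, sigma_minus, mu_plus,
#'   sigma_plus)`: the normalized movement-time change following a reward
#'   decrement / increment is drawn from the corresponding Gaussian. All
#'   zeros disables coupling.
#' @param error_rate probability any given trial is an error.
#' @param variable_show_prob probability a score is shown on a
#'   variable-schedule trial.
#' @param extinction_day first study day without reward feedback.
#' @param diurnal per-group named vectors `c(mean_hour, kappa)` of the von
#'   Mises distribution of participant-preferred practice hours.
#' @param kappa_within concentration of a participant's session hours around
#'   their own preferred hour.
#' @param score_scale numerator of [score_function()].
#' @param mt_floor lower bound on generated movement times (seconds).
#' @param start_date calendar date of study day 1.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(
    n_per_group = c(HV = 33L, OCD = 32L),
    days = 30L,
    practices_per_day = 2L,
    trials_per_practice = 20L,
    schedules = c("continuous", "variable"),
    learning = list(HV = c(mt0 = 1.7, mtl = 3.1, nr = 176),
                    OCD = c(mt0 = 1.8, mtl = 3.9, nr = 200)),
    automaticity = list(HV = c(c0 = 0.287, cl = 1.4, nc = 142),
                        OCD = c(c0 = 0.301, cl = 1.9, nc = 198)),
    param_sdlog = c(mt0 = 0.17, mtl = 0.29, nr = 0.42,
                    c0 = 0.33, cl = 0.37, nc = 0.64),
    mt_noise_cv = 0.05,
    c_noise_cv = 0.10,
    iki_profile = c(0.18, 0.22, 0.20, 0.22, 0.18),
    reward_coupling = c(mu_minus = -0.05, sigma_minus = 0.02,
                        mu_plus = -0.01, sigma_plus = 0.02),
    error_rate = 0.1,
    variable_show_prob = 0.37,
    extinction_day = 21L,
    diurnal = list(HV = c(mean_hour = 15, kappa = vonmises_kappa(0.47)),
                   OCD = c(mean_hour = 18, kappa = vonmises_kappa(0.58))),
    kappa_within = 2,
    score_scale = 100,
    mt_floor = 0.3,
    start_date = "2023-01-01") {
  # accept list forms (e.g. from YAML) for every named-vector field
  vec <- function(x) if (is.list(x)) unlist(x) else x
  n_per_group <- vec(n_per_group)
  param_sdlog <- vec(param_sdlog)
  iki_profile <- vec(iki_profile)
  reward_coupling <- vec(reward_coupling)
  learning <- lapply(learning, vec)
  automaticity <- lapply(automaticity, vec)
  diurnal <- lapply(diurnal, vec)
  schedules <- vec(schedules)
  n_per_group <- setNames(as.integer(n_per_group), names(n_per_group))
  cfg <- list(n_per_group = n_per_group, days = as.integer(days),
              practices_per_day = as.integer(practices_per_day),
              trials_per_practice = as.integer(trials_per_practice),
              schedules = schedules, learning = learning,
              automaticity = automaticity, param_sdlog = param_sdlog,
              mt_noise_cv = mt_noise_cv, c_noise_cv = c_noise_cv,
              iki_profile = iki_profile, reward_coupling = reward_coupling,
              error_rate = error_rate,
              variable_show_prob = variable_show_prob,
              extinction_day = as.integer(extinction_day),
              diurnal = diurnal, kappa_within = kappa_within,
              score_scale = score_scale, mt_floor = mt_floor,
              start_date = as.Date(start_date))
  groups <- names(cfg$n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("generator config error: n_per_group must be a named vector")
  }
  if (any(cfg$n_per_group < 0)) {
    stop("generator config error: negative cohort size")
  }
  if (cfg$days < 1 || cfg$practices_per_day < 1 ||
      cfg$trials_per_practice < 1) {
    stop("generator config error: days/practices/trials must be >= 1")
  }
  if (!all(cfg$schedules %in% c("continuous", "variable")) ||
      !length(cfg$schedules)) {
    stop("generator config error: schedules must be a subset of ",
         "continuous/variable")
  }
  for (g in groups) {
    if (!all(c("mt0", "mtl", "nr") %in% names(cfg$learning[[g]])) ||
        !all(c("c0", "cl", "nc") %in% names(cfg$automaticity[[g]])) ||
        !all(c("mean_hour", "kappa") %in% names(cfg$diurnal[[g]]))) {
      stop("generator config error: missing parameters for group ", g)
    }
    if (any(cfg$learning[[g]] <= 0) || any(cfg$automaticity[[g]] <= 0)) {
      stop("generator config error: decay parameters must be positive")
    }
    if (cfg$diurnal[[g]][["kappa"]] < 0) {
      stop("generator config error: diurnal kappa must be >= 0")
    }
  }
  probs <- c(cfg$error_rate, cfg$variable_show_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("generator config error: rates/probabilities must lie in [0, 1]")
  }
  if (length(cfg$iki_profile) != 5L || any(cfg$iki_profile <= 0) ||
      abs(sum(cfg$iki_profile) - 1) > 1e-8) {
    stop("generator config error: iki_profile must be 5 positive ",
         "proportions summing to 1")
  }
  if (any(cfg$reward_coupling[c("sigma_minus", "sigma_plus")] < 0)) {
    stop("generator config error: coupling sigmas must be >= 0")
  }
  if (any(cfg$param_sdlog < 0) || cfg$mt_noise_cv < 0 || cfg$c_noise_cv < 0) {
    stop("generator config error: spreads must be >= 0")
  }
  if (cfg$kappa_within < 0) {
    stop("generator config error: kappa_within must be >= 0")
  }
  if (cfg$mt_floor <= 0) {
    stop("generator config error: mt_floor must be positive")
  }
  structure(cfg, class = "generator_config")
}

# Movement-time chain with reward coupling. On a transition whose preceding
# reward change (computed from *shown* scores) had a nonzero sign, the next
# movement time is mt[n] * (1 + delta) with delta ~ N(mu_sign, sigma_sign);
# on zero-sign, hidden-score or first transitions it resets to the backbone.
# Realized normalized changes after signed transitions are therefore exact
# Gaussian draws, while the backbone resets keep the marginal trend on the
# exponential curve.
.couple_mt_chain <- function(mt_base, shown, coupling, score_scale,
                             mt_floor) {
  N <- length(mt_base)
  off <- all(coupling == 0)
  score <- score_function(mt_base, score_scale)
  if (off || N < 2L) {
    return(list(mt = mt_base, score = ifelse(shown, score, NA_real_)))
  }
  mt <- mt_base
  # pre-drawn perturbations keep the inner loop cheap and deterministic
  d_plus <- rnorm(N, coupling[["mu_plus"]], coupling[["sigma_plus"]])
  d_minus <- rnorm(N, coupling[["mu_minus"]], coupling[["sigma_minus"]])
  score[1L] <- round(score_scale / mt[1L])
  sign_prev <- 0L
  for (n in 2:N) {
    if (sign_prev > 0L) {
      mt[n] <- max(mt_floor, mt[n - 1L] * (1 + d_plus[n]))
    } else if (sign_prev < 0L) {
      mt[n] <- max(mt_floor, mt[n - 1L] * (1 + d_minus[n]))
    } # else keep the backbone value
    score[n] <- round(score_scale / mt[n])
    sign_prev <- if (shown[n] && shown[n - 1L]) {
      sign(score[n] - score[n - 1L])
    } else 0L
  }
  score <- pmax(score, 0)
  list(mt = mt, score = ifelse(shown, score, NA_real_))
}

# Solve sum_k |a_k + lambda * v_k| = target for lambda >= 0. The objective
# is convex and piecewise linear with minimum sum|a| at lambda = 0 (v is
# zero-sum, a has constant sign), so the solution is unique when feasible;
# returns 0 when target < sum|a|.
.solve_c_scale <- function(a, v, target) {
  f0 <- sum(abs(a))
  if (target <= f0) return(0)
  bp <- -a / v
  bp <- sort(bp[is.finite(bp) & bp > 0])
  lam_prev <- 0
  f_prev <- f0
  for (lam in c(bp, Inf)) {
    mid <- if (is.finite(lam)) (lam_prev + lam) / 2 else lam_prev + 1
    slope <- sum(v * sign(a + mid * v))
    if (slope > 0) {
      lam_hit <- lam_prev + (target - f_prev) / slope
      if (lam_hit <= lam) return(lam_hit)
    }
    if (is.finite(lam)) f_prev <- f_prev + slope * (lam - lam_prev)
    lam_prev <- lam
  }
  lam_prev # unreachable: terminal slope sum|v| > 0 always hits the target
}

# Build IKI rows (N x 5) for a movement-time series so that (i) every row
# sums exactly to mt[n] and (ii) the consistency index between rows n and
# n+1 equals target_c[n] whenever the movement-time difference leaves that
# feasible. Row deviations from the base profile follow a mean-reverting
# zero-sum walk so intervals stay positive and bounded.
.build_iki_rows <- function(mt, profile, target_c, min_frac = 0.05) {
  N <- length(mt)
  iki <- matrix(0, N, 5L)
  d <- numeric(5L)
  iki[1L, ] <- mt[1L] * profile
  if (N < 2L) return(iki)
  Z <- matrix(rnorm(5L * (N - 1L)), N - 1L, 5L)
  for (n in 1:(N - 1L)) {
    a <- (mt[n + 1L] - mt[n]) * profile
    u <- Z[n, ]
    u <- u - mean(u)
    nd <- sqrt(sum(d^2))
    if (nd > 1e-12) {
      w <- min(0.9, nd / (nd + target_c[n] / 2))
      u <- (1 - w) * u / sqrt(sum(u^2)) - w * d / nd
    }
    u <- u - mean(u)
    u <- u / sqrt(sum(u^2))
    lam_target <- .solve_c_scale(a, u, target_c[n])
    # keep every interval above min_frac of its nominal share; when the
    # constraint binds, the reflected direction may leave more room
    nominal <- mt[n + 1L] * profile
    room <- nominal + d - min_frac * nominal
    allowed <- function(v) {
      neg <- v < 0
      if (any(neg)) max(min(room[neg] / -v[neg]), 0) else Inf
    }
    lam_u <- allowed(u)
    if (lam_u < lam_target) {
      lam_r <- allowed(-u)
      if (min(lam_r, .solve_c_scale(a, -u, target_c[n])) >
          min(lam_u, lam_target)) {
        u <- -u
        lam_target <- .solve_c_scale(a, u, target_c[n])
        lam_u <- lam_r
      }
    }
    lam <- min(lam_target, lam_u)
    d <- d + lam * u
    d <- d - mean(d) # kill numeric zero-sum drift
    row <- nominal + d
    minv <- min_frac * nominal
    if (any(row < minv)) {
      # a shrinking movement time can leave carried deviations below the
      # floor; lift offending intervals and take the lift from the others
      # proportionally to their headroom, preserving the exact row sum
      lift <- sum(pmax(minv - row, 0))
      row <- pmax(row, minv)
      excess <- row - minv
      row <- row - lift * excess / sum(excess)
      d <- row - nominal
    }
    iki[n + 1L, ] <- row
  }
  iki
}

#' Generate a synthetic training cohort
#'
#' Produces a full `study_dataset` (per-trial keystroke log) plus the
#' ground-truth table of every participant's true learning, automaticity and
#' diurnal parameters. Generation is a pure function of `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; required for reproducibility.
#' @return list with elements `dataset` (a `study_dataset`) and `truth`
#'   (data.frame: `participant_id`, `group`, `mt0`, `mtl`, `nr`, `c0`, `cl`,
#'   `nc`, `mean_hour`).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  tpp <- config$trials_per_practice
  ppd <- config$practices_per_day
  N <- config$days * ppd * tpp
  n_practices <- config$days * ppd
  sdl_mt <- sqrt(log(1 + config$mt_noise_cv^2))
  sdl_c <- sqrt(log(1 + config$c_noise_cv^2))
  truth <- list()
  blocks <- list()
  for (g in names(config$n_per_group)) {
    lg <- config$learning[[g]]
    ag <- config$automaticity[[g]]
    dg <- config$diurnal[[g]]
    for (i in seq_len(config$n_per_group[[g]])) {
      pid <- sprintf("%s%03d", g, i)
      draw <- function(med, nm) med * exp(rnorm(1, 0, config$param_sdlog[[nm]]))
      pars <- c(mt0 = draw(lg[["mt0"]], "mt0"), mtl = draw(lg[["mtl"]], "mtl"),
                nr = draw(lg[["nr"]], "nr"), c0 = draw(ag[["c0"]], "c0"),
                cl = draw(ag[["cl"]], "cl"), nc = draw(ag[["nc"]], "nc"))
      mean_hour <- rvonmises(1, dg[["mean_hour"]] * pi / 12,
                             dg[["kappa"]]) * 12 / pi
      truth[[pid]] <- data.frame(participant_id = pid, group = g,
                                 t(pars), mean_hour = mean_hour)
      for (sched in config$schedules) {
        n <- seq_len(N)
        backbone <- .exp_decay(n, pars[["mt0"]], pars[["mtl"]], pars[["nr"]])
        eps <- exp(rnorm(N, -sdl_mt^2 / 2, sdl_mt))
        mt_base <- pmax(config$mt_floor, backbone * eps)
        practice <- ceiling(n / tpp)
        day <- ceiling(practice / ppd)
        shown <- if (sched == "continuous") {
          day < config$extinction_day
        } else {
          day < config$extinction_day &
            runif(N) < config$variable_show_prob
        }
        cs <- .couple_mt_chain(mt_base, shown, config$reward_coupling,
                               config$score_scale, config$mt_floor)
        target_c <- .exp_decay(seq_len(max(N - 1L, 1L)), pars[["c0"]],
                               pars[["cl"]], pars[["nc"]]) *
          exp(rnorm(max(N - 1L, 1L), -sdl_c^2 / 2, sdl_c))
        iki <- .build_iki_rows(cs$mt, config$iki_profile, target_c)
        press <- cbind(0, t(apply(iki, 1L, cumsum)))
        err_before <- if (config$error_rate > 0) {
          rgeom(N, 1 - config$error_rate)
        } else integer(N)
        rows_per <- err_before + 1L
        M <- sum(rows_per)
        is_corr <- logical(M)
        is_corr[cumsum(rows_per)] <- TRUE
        corr_of_row <- rep(n, rows_per)
        sess <- practice[corr_of_row]
        row_day <- day[corr_of_row]
        hours <- rvonmises(n_practices, mean_hour * pi / 12,
                           config$kappa_within) * 12 / pi
        # practices within a day happen in clock order, so the session
        # counter stays chronological
        hours <- as.vector(apply(matrix(hours, nrow = ppd), 2L, sort))
        sess_start <- as.POSIXct(config$start_date, tz = "UTC") +
          (ceiling(seq_len(n_practices) / ppd) - 1) * 86400 +
          round(hours * 3600)
        pm <- matrix(NA_real_, M, 6L)
        pm[is_corr, ] <- press
        sc <- rep(NA_real_, M)
        sc[is_corr] <- cs$score
        blk <- data.frame(
          participant_id = pid, group = g, schedule = sched,
          session_id = sess,
          session_start = sess_start[sess],
          study_day = row_day,
          trial = stats::ave(seq_len(M), sess, FUN = seq_along),
          trial_outcome = ifelse(is_corr, "correct", "error"))
        blk[paste0("t", 1:6)] <- pm
        blk$score <- sc
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
  }
  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(dataset = study_dataset(trials,
                               extinction_day = config$extinction_day,
                               min_daily_practices = ppd,
                               trials_per_practice = tpp,
                               validate = FALSE),
       truth = truth_df)
}

#' Inject reward coupling into a trial series
#'
#' Rewrites the movement times of a correct-trial series so that the
#' normalized movement-time change following a reward decrement / increment
#' is an exact draw from `N(mu_minus, sigma_minus)` / `N(mu_plus,
#' sigma_plus)`, applied multiplicatively and floored at `mt_floor`.
#' Transitions with a zero or undefined reward change keep their original
#' movement time. Scores are recomputed trial by trial from the modified
#' movement times with the trial's original shown/hidden status; IKI rows
#' are rescaled proportionally so that all series invariants continue to
#' hold. An all-zero `coupling` returns the series unchanged; a series
#' without any scores is returned unchanged with a warning.
#'
#' @param series a `trial_series`.
#' @param coupling named vector `c(mu_minus, sigma_minus, mu_plus,
#'   sigma_plus)`.
#' @param seed integer seed for the Gaussian draws.
#' @param score_scale numerator of [score_function()].
#' @param mt_floor lower bound on movement times (seconds).
#' @return the modified `trial_series`.
#' @export
inject_reward_coupling <- function(series, coupling, seed = 1L,
                                   score_scale = 100, mt_floor = 0.3) {
  stopifnot(inherits(series, "trial_series"))
  if (any(coupling[c("sigma_minus", "sigma_plus")] < 0)) {
    stop("coupling sigmas must be >= 0")
  }
  if (all(is.na(series$score))) {
    warning("series has no scores: reward change undefined, series unchanged")
    return(series)
  }
  if (all(coupling == 0)) return(series)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  shown <- !is.na(series$score)
  cs <- .couple_mt_chain(series$mt, shown, coupling, score_scale, mt_floor)
  scale <- cs$mt / series$mt
  series$mt <- cs$mt
  series$iki <- series$iki * scale
  series$score <- cs$score
  series
}
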
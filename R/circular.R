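# Circular statistics of practice timing: hours-of-day embedded on the unit
# circle, per-participant mean resultant vectors, Rayleigh uniformity test,
# and the two-sample Watson U2 test.

#' Convert hours of day to angles
#'
#' Embeds clock time on the unit circle: `theta = 2 * pi * h / 24`.
#'
#' @param hours numeric vector in \[0, 24).
#' @return angles in radians, \[0, 2*pi).
#' @export
hours_to_angles <- function(hours) {
  if (anyNA(hours) || any(hours < 0 | hours >= 24)) {
    stop("hours must lie in [0, 24)")
  }
  2 * pi * hours / 24
}

#' Convert angles to hours of day
#'
#' Inverse of [hours_to_angles()].
#'
#' @param angles radians.
#' @return hours in \[0, 24).
#' @export
angles_to_hours <- function(angles) {
  (angles %% (2 * pi)) * 24 / (2 * pi)
}

#' Mean resultant vector of a circular sample
#'
#' @param angles radians; at least one value.
#' @return list with `r` (mean resultant length in \[0, 1\]) and
#'   `mean_direction` (radians in \[0, 2*pi)).
#' @export
mean_vector <- function(angles) {
  if (!length(angles) || anyNA(angles)) {
    stop("angles must be a non-empty numeric vector")
  }
  cbar <- mean(cos(angles))
  sbar <- mean(sin(angles))
  list(r = min(sqrt(cbar^2 + sbar^2), 1),
       mean_direction = atan2(sbar, cbar) %% (2 * pi))
}

#' Rayleigh test of circular uniformity
#'
#' Tests uniformity of angles on the circle against a unimodal alternative:
#' `Z = n * rbar^2` with the standard series approximation of the p-value,
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clipped into (0, 1].
#'
#' @param angles radians; a warning is issued below n = 4 where the
#'   approximation is poor.
#' @return object of class `circular_summary`: list with `n`, `r`
#'   (mean resultant length), `mean_direction` (radians),
#'   `mean_direction_hours`, `statistic` (Z), `p_value`.
#' @export
rayleigh_test <- function(angles) {
  if (!length(angles)) stop("empty circular sample")
  n <- length(angles)
  if (n < 4L) warning("Rayleigh approximation unreliable for n < 4")
  mv <- mean_vector(angles)
  Z <- n * mv$r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                    (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n = n, r = mv$r, mean_direction = mv$mean_direction,
                 mean_direction_hours = angles_to_hours(mv$mean_direction),
                 statistic = Z, p_value = p),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n = %d, Rbar = %.3f, mean direction %.2f h, Z = %.3f, p = %.3g\n",
    x$n, x$r, x$mean_direction_hours, x$statistic, x$p_value))
  invisible(x)
}

# Rank-based two-sample Watson U2 statistic. Cumulative fractions of both
# samples are evaluated at every point of the pooled sorted sample (tied
# values collapse to one evaluation point, weighted by their multiplicity).
.watson_u2_stat <- function(a, b) {
  n <- length(a)
  m <- length(b)
  N <- n + m
  vals <- sort(unique(c(a, b)))
  ca <- findInterval(vals, sort(a)) / n
  cb <- findInterval(vals, sort(b)) / m
  w <- tabulate(match(c(a, b), vals), nbins = length(vals))
  d <- ca - cb
  dbar <- sum(d * w) / N
  (n * m / N^2) * sum(w * (d - dbar)^2)
}

#' Watson's two-sample U2 test for circular data
#'
#' Nonparametric rank-based test of whether two circular samples come from
#' a common distribution. The statistic is the standard two-sample Watson
#' U2; the primary p-value is obtained by a seeded permutation of group
#' labels (exact under exchangeability), with the classical asymptotic
#' critical-value bracket reported alongside for comparability.
#'
#' @param angles_a,angles_b circular samples in radians (each n >= 8 for the
#'   critical-value bracket to be meaningful; smaller samples only warn).
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return list with `statistic` (U2), `p_value` (permutation), `n_perm`,
#'   `bracket` (character, decision bracket from the classical critical
#'   values), `n_a`, `n_b`.
#' @export
watson_two_test <- function(angles_a, angles_b, n_perm = 9999L, seed = 1L) {
  if (length(angles_a) < 8L || length(angles_b) < 8L) {
    warning("Watson U2 critical values unreliable for n < 8")
  }
  a <- angles_a %% (2 * pi)
  b <- angles_b %% (2 * pi)
  u2 <- .watson_u2_stat(a, b)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  pooled <- c(a, b)
  n <- length(a)
  N <- length(pooled)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(N, n)
    if (.watson_u2_stat(pooled[idx], pooled[-idx]) >= u2 - 1e-12) {
      exceed <- exceed + 1L
    }
  }
  p <- (exceed + 1L) / (n_perm + 1L)
  crit <- c("0.10" = 0.152, "0.05" = 0.187, "0.01" = 0.268,
            "0.001" = 0.385)
  above <- names(crit)[u2 > crit]
  bracket <- if (!length(above)) "p > 0.10" else
    paste0("p < ", above[length(above)])
  list(statistic = u2, p_value = p, n_perm = as.integer(n_perm),
       bracket = bracket, n_a = length(a), n_b = length(b))
}

#' Preferred practice hour of every participant
#'
#' Computes, per participant, the mean direction of the start hours of all
#' practice sessions (one angle per session; every practice of both
#' schedules contributes). The returned participant-level mean directions
#' are the natural input for a group-level Rayleigh test, one dot per
#' participant on the unit circle.
#'
#' @param dataset a `study_dataset`.
#' @return data.frame with `participant_id`, `group`, `n_sessions`,
#'   `mean_hour`, `r` (participant-level mean resultant length).
#' @export
participant_mean_hours <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  tr <- dataset$trials
  key <- !duplicated(tr[, c("participant_id", "schedule", "session_id")])
  sess <- tr[key, c("participant_id", "group", "session_start")]
  lt <- as.POSIXlt(sess$session_start, tz = "UTC")
  hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  ang <- hours_to_angles(hours)
  out <- lapply(split(seq_len(nrow(sess)), sess$participant_id), function(ix) {
    mv <- mean_vector(ang[ix])
    data.frame(participant_id = sess$participant_id[ix[1L]],
               group = sess$group[ix[1L]], n_sessions = length(ix),
               mean_hour = angles_to_hours(mv$mean_direction), r = mv$r)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
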
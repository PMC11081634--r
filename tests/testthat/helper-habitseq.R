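# Shared fixtures, all built in code.

# Minimal hand-written trial table: `press` is a list of 6-vectors (or NULL
# for error trials), `score` may contain NA.
make_trials <- function(press, outcome = NULL, score = NULL,
                        participant_id = "P1", group = "HV",
                        schedule = "continuous", session_id = 1L,
                        study_day = 1L,
                        session_start = "2023-01-01T10:00:00") {
  k <- length(press)
  if (is.null(outcome)) {
    outcome <- ifelse(vapply(press, is.null, TRUE), "error", "correct")
  }
  if (is.null(score)) score <- rep(NA_real_, k)
  tr <- data.frame(
    participant_id = rep_len(participant_id, k),
    group = rep_len(group, k),
    schedule = rep_len(schedule, k),
    session_id = rep_len(as.integer(session_id), k),
    session_start = rep_len(session_start, k),
    study_day = rep_len(as.integer(study_day), k),
    trial = seq_len(k),
    trial_outcome = outcome)
  pm <- t(vapply(press, function(p) {
    if (is.null(p)) rep(NA_real_, 6) else as.numeric(p)
  }, numeric(6)))
  tr[paste0("t", 1:6)] <- pm
  tr$score <- as.numeric(score)
  tr
}

# Press-time vector with given movement time and a fixed IKI profile.
press_for_mt <- function(mt, profile = c(0.18, 0.22, 0.20, 0.22, 0.18)) {
  cumsum(c(0, mt * profile))
}

# Coupling vectors used across tests.
coupling_off <- c(mu_minus = 0, sigma_minus = 0, mu_plus = 0, sigma_plus = 0)
coupling_ref <- c(mu_minus = -0.05, sigma_minus = 0.02,
                  mu_plus = -0.01, sigma_plus = 0.02)

# Small synthetic cohort, memoised per options so several tests can share it.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 1L, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- generator_config(...)
    .cohort_cache[[key]] <- generate_cohort(cfg, seed = seed)
  }
  .cohort_cache[[key]]
}
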
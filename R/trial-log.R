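# Trial-log data model: documented tabular dialect for per-trial keystroke
# logs, validation, and construction of per-participant correct-trial series.
#
# One row per app trial. Columns (the data dictionary):
#   participant_id  opaque string
#   group           cohort label, e.g. "HV" / "OCD"
#   schedule        "continuous" or "variable" reward schedule
#   session_id      1-based practice session counter within participant x
#                   schedule
#   session_start   wall-clock start of the session, ISO-8601 UTC
#   study_day       1-based day of training
#   trial           1-based trial counter within the session (includes errors)
#   trial_outcome   "correct" or "error"
#   t1..t6          key-press timestamps in seconds on a within-trial clock;
#                   present iff the trial is correct
#   score           points shown on the trial; empty when no feedback was
#                   displayed (variable-schedule unshown trials, extinction)

.trial_log_required <- c(
  "participant_id", "group", "schedule", "session_id", "session_start",
  "study_day", "trial", "trial_outcome",
  paste0("t", 1:6), "score"
)

.press_cols <- paste0("t", 1:6)

.iso8601 <- "%Y-%m-%dT%H:%M:%S"

#' Construct a study dataset from a trial table
#'
#' Bundles a table of per-trial records with study-level metadata and
#' (optionally) validates every row against the trial-log invariants.
#'
#' @param trials data.frame with the trial-log columns (see
#'   [read_trial_log()] for the data dictionary).
#' @param extinction_day first study day on which reward feedback was
#'   removed; `Inf` disables the extinction invariant.
#' @param min_daily_practices minimum required practices per sequence per day
#'   (metadata only).
#' @param trials_per_practice number of correct trials that complete one
#'   practice session.
#' @param validate if `TRUE`, row-level violations raise an error (warnings
#'   are reported as warnings).
#' @return an object of class `study_dataset`: a list with elements `trials`
#'   (the validated data.frame) and `metadata`.
#' @seealso [validate_trial_log()], [build_trial_series()]
#' @export
study_dataset <- function(trials, extinction_day = 21,
                          min_daily_practices = 2, trials_per_practice = 20,
                          validate = TRUE) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(.trial_log_required, names(trials))
  if (length(missing_cols)) {
    stop("trial log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- trials[, .trial_log_required]
  trials$participant_id <- as.character(trials$participant_id)
  trials$group <- as.character(trials$group)
  trials$schedule <- as.character(trials$schedule)
  trials$session_id <- as.integer(trials$session_id)
  trials$study_day <- as.integer(trials$study_day)
  trials$trial <- as.integer(trials$trial)
  trials$trial_outcome <- as.character(trials$trial_outcome)
  for (cc in c(.press_cols, "score")) trials[[cc]] <- as.numeric(trials[[cc]])
  if (!inherits(trials$session_start, "POSIXct")) {
    trials$session_start <- as.POSIXct(as.character(trials$session_start),
                                       format = .iso8601, tz = "UTC")
  }
  x <- structure(
    list(trials = trials,
         metadata = list(extinction_day = extinction_day,
                         min_daily_practices = min_daily_practices,
                         trials_per_practice = trials_per_practice)),
    class = "study_dataset")
  if (validate) {
    issues <- validate_trial_log(x)
    errs <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(errs)) {
      stop("trial log validation failed:\n",
           paste(sprintf("  row %s: %s", errs$row, errs$message),
                 collapse = "\n"))
    }
    warns <- issues[issues$severity == "warning", , drop = FALSE]
    if (nrow(warns)) {
      warning(sprintf("%d trial-log warning(s), e.g. row %s: %s",
                      nrow(warns), warns$row[1], warns$message[1]))
    }
  }
  x
}

#' Validate a study dataset against the trial-log invariants
#'
#' Collects (rather than raises) all row-level violations: press-time
#' cardinality and monotonicity on correct trials, score present during
#' extinction, negative scores, malformed session indices. A missing score
#' on a pre-extinction continuous-schedule trial is reported as a warning
#' only, since real logs may drop packets.
#'
#' @param dataset a `study_dataset`.
#' @return data.frame with columns `row`, `severity` ("error"/"warning"),
#'   `message`; zero rows when the dataset is clean.
#' @export
validate_trial_log <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  tr <- dataset$trials
  ext <- dataset$metadata$extinction_day
  issues <- list()
  add <- function(rows, severity, message) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<-
        data.frame(row = rows, severity = severity, message = message)
    }
  }
  bad_outcome <- which(!tr$trial_outcome %in% c("correct", "error"))
  add(bad_outcome, "error", "trial_outcome must be 'correct' or 'error'")
  press <- as.matrix(tr[, .press_cols])
  n_press <- rowSums(!is.na(press))
  corr <- tr$trial_outcome == "correct"
  add(which(corr & n_press != 6L), "error",
      "correct trial must carry exactly 6 press timestamps")
  complete <- corr & n_press == 6L
  if (any(complete)) {
    nondec <- which(complete)[apply(press[complete, , drop = FALSE], 1L,
                                    function(p) any(diff(p) <= 0))]
    add(nondec, "error", "press timestamps must be strictly increasing")
  }
  add(which(!is.na(tr$score) & tr$score < 0), "error",
      "score must be nonnegative")
  add(which(is.na(tr$session_id) | tr$session_id < 1L), "error",
      "session_id must be an integer >= 1")
  add(which(is.na(tr$study_day) | tr$study_day < 1L), "error",
      "study_day must be an integer >= 1")
  add(which(is.na(tr$session_start)), "error",
      "session_start must be a valid ISO-8601 datetime")
  if (is.finite(ext)) {
    add(which(tr$study_day >= ext & !is.na(tr$score)), "error",
        sprintf("score shown on extinction-phase trial (study_day >= %s)",
                ext))
  }
  add(which(corr & tr$schedule == "continuous" & tr$study_day < ext &
              is.na(tr$score)), "warning",
      "missing score on pre-extinction continuous-schedule trial")
  if (!length(issues)) {
    return(data.frame(row = integer(), severity = character(),
                      message = character()))
  }
  out <- do.call(rbind, issues)
  out[order(out$row), , drop = FALSE]
}

#' @export
print.study_dataset <- function(x, ...) {
  tr <- x$trials
  cat(sprintf(
    "<study_dataset> %d trials, %d participants, %d correct\n",
    nrow(tr), length(unique(tr$participant_id)),
    sum(tr$trial_outcome == "correct")))
  cat(sprintf("  groups: %s | schedules: %s | extinction day: %s\n",
              paste(sort(unique(tr$group)), collapse = "/"),
              paste(sort(unique(tr$schedule)), collapse = "/"),
              format(x$metadata$extinction_day)))
  invisible(x)
}

# full-precision numeric formatting so that read(write(x)) is bit-faithful
.fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
  out
}

#' Write a study dataset to a trial-log file
#'
#' Serialises a `study_dataset` to the documented CSV dialect (RFC 4180,
#' one row per trial) or to JSON-lines (one JSON object per trial). Absent
#' values (press times on error trials, unshown scores) are written as empty
#' cells / omitted keys, never as 0. Numeric columns are written with full
#' double precision so that [read_trial_log()] recovers the dataset exactly.
#'
#' @param dataset a `study_dataset`.
#' @param path output file path; format inferred from the extension
#'   (".csv" or ".jsonl") unless `format` is given.
#' @param format "auto", "csv" or "jsonl".
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(dataset, path, format = c("auto", "csv", "jsonl")) {
  stopifnot(inherits(dataset, "study_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  tr <- dataset$trials
  out <- tr
  out$session_start <- format(tr$session_start, paste0(.iso8601, "Z"),
                              tz = "UTC")
  for (cc in c(.press_cols, "score")) out[[cc]] <- .fmt_num(tr[[cc]])
  if (format == "csv") {
    ok <- tryCatch({
      suppressWarnings(
        write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write trial log to '", path, "': ",
                          conditionMessage(ok))
  } else {
    con <- tryCatch(file(path, "w"), error = function(e) e)
    if (inherits(con, "error")) {
      stop("cannot write trial log to '", path, "': ",
           conditionMessage(con))
    }
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      rec <- as.list(out[i, ])
      rec <- rec[!vapply(rec, function(v) identical(v, ""), TRUE)]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Read a trial log
#'
#' Reads the documented trial-log dialect (CSV or JSON-lines; see
#' [write_trial_log()] for the data dictionary) and validates every row.
#'
#' @param path file path.
#' @param format "auto", "csv" or "jsonl".
#' @inheritParams study_dataset
#' @return a validated `study_dataset`.
#' @export
read_trial_log <- function(path, format = c("auto", "csv", "jsonl"),
                           extinction_day = 21, min_daily_practices = 2,
                           trials_per_practice = 20, validate = TRUE) {
  if (!file.exists(path)) stop("trial log not found: '", path, "'")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
    if (nrow(raw)) {
      for (cc in c(.press_cols, "score")) raw[[cc]] <- as.numeric(raw[[cc]])
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      for (cc in setdiff(.trial_log_required, names(rec))) rec[[cc]] <- NA
      as.data.frame(rec[.trial_log_required], stringsAsFactors = FALSE)
    })
    raw <- if (length(recs)) do.call(rbind, recs) else
      setNames(as.data.frame(matrix(nrow = 0, ncol =
                                      length(.trial_log_required))),
               .trial_log_required)
  }
  study_dataset(raw, extinction_day = extinction_day,
                min_daily_practices = min_daily_practices,
                trials_per_practice = trials_per_practice,
                validate = validate)
}

#' Build the ordered correct-trial series of one participant
#'
#' Extracts all correct trials of one participant under one reward schedule,
#' in chronological order across sessions, and derives the movement-time
#' series `MT(n) = t6 - t1` and the 5-column matrix of inter-keystroke
#' intervals. Error trials never enter the series: the trial counter `n`
#' runs over correct trials only.
#'
#' @param dataset a `study_dataset`.
#' @param participant_id participant identifier present in the dataset.
#' @param schedule reward schedule, "continuous" or "variable".
#' @return an object of class `trial_series`: list with `participant_id`,
#'   `group`, `schedule`, `n_index`, `mt` (seconds), `iki` (n x 5 matrix,
#'   seconds), `score` (may contain `NA`), `session_id`, `study_day`.
#' @export
build_trial_series <- function(dataset, participant_id, schedule) {
  stopifnot(inherits(dataset, "study_dataset"))
  tr <- dataset$trials
  sel <- tr$participant_id == participant_id & tr$schedule == schedule
  if (!any(sel)) {
    stop("no trials for participant '", participant_id,
         "' under schedule '", schedule, "'")
  }
  tr <- tr[sel, , drop = FALSE]
  tr <- tr[order(tr$session_start, tr$session_id, tr$trial), , drop = FALSE]
  tr <- tr[tr$trial_outcome == "correct", , drop = FALSE]
  press <- as.matrix(tr[, .press_cols])
  iki <- press[, 2:6, drop = FALSE] - press[, 1:5, drop = FALSE]
  colnames(iki) <- paste0("iki", 1:5)
  structure(
    list(participant_id = participant_id,
         group = if (nrow(tr)) tr$group[1] else NA_character_,
         schedule = schedule,
         n_index = seq_len(nrow(tr)),
         mt = unname(press[, 6] - press[, 1]),
         iki = unname(iki),
         score = tr$score,
         session_id = tr$session_id,
         study_day = tr$study_day),
    class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf(
    "<trial_series> %s [%s, %s]: %d correct trials, median MT %.3f s\n",
    x$participant_id, x$group, x$schedule, length(x$mt),
    if (length(x$mt)) median(x$mt) else NA))
  invisible(x)
}

#' Count completed practices of a participant
#'
#' A practice is a session of `trials_per_practice` (default 20) correct
#' trials. With `method = "trials"` (default), the count is
#' `floor(correct trials / trials_per_practice)` per schedule, summed over
#' schedules; with `method = "sessions"` the explicit session ids are used
#' and every session with at least `trials_per_practice` correct trials
#' counts as one practice.
#'
#' @param dataset a `study_dataset`.
#' @param participant_id participant identifier.
#' @param method "trials" or "sessions".
#' @return integer practice count.
#' @export
count_practices <- function(dataset, participant_id,
                            method = c("trials", "sessions")) {
  stopifnot(inherits(dataset, "study_dataset"))
  method <- match.arg(method)
  tpp <- dataset$metadata$trials_per_practice
  tr <- dataset$trials
  tr <- tr[tr$participant_id == participant_id, , drop = FALSE]
  if (!nrow(tr)) stop("unknown participant '", participant_id, "'")
  tr <- tr[tr$trial_outcome == "correct", , drop = FALSE]
  if (!nrow(tr)) return(0L)
  if (method == "trials") {
    n_corr <- table(tr$schedule)
    return(as.integer(sum(n_corr %/% tpp)))
  }
  key <- interaction(tr$schedule, tr$session_id, drop = TRUE)
  as.integer(sum(table(key) >= tpp))
}
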
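# Group-level inference over fitted parameters and sensitivity summaries:
# Kruskal-Wallis H, three-way mixed ANOVA (two within-participant factors,
# one between-group factor), dependent-sample t-tests, and
# Benjamini-Hochberg FDR control.

.test_result <- function(effect, statistic, df1, df2, p, family = NA_character_,
                         note = NA_character_) {
  data.frame(effect = effect, statistic = statistic, df1 = df1, df2 = df2,
             p = p, p_fdr = NA_real_, family = family, note = note)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value (delegates to
#' [stats::kruskal.test()]), returned as a tidy one-row test-result table.
#'
#' @param values numeric response.
#' @param labels grouping with at least two groups of n >= 2 each.
#' @param effect label for the result row.
#' @return data.frame with `effect`, `statistic` (H), `df1`, `df2` (NA),
#'   `p`, `p_fdr` (NA until [fdr_bh()] is applied), `family`, `note`.
#' @export
kruskal_wallis <- function(values, labels, effect = "group") {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  kt <- kruskal.test(values, labels)
  .test_result(effect, unname(kt$statistic), unname(kt$parameter), NA_real_,
               kt$p.value)
}

#' Three-way mixed ANOVA
#'
#' Standard mixed-design decomposition for two within-participant factors
#' and one between-participant factor, via [stats::aov()] with participant
#' error strata (`Error(subject / (w1 * w2))`). Participants missing any
#' within-cell are dropped listwise with a message. No sphericity
#' correction is applied (plain F and df are reported).
#'
#' @param table long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of the two within-participant factor
#'   columns.
#' @param between name of the between-participant factor column.
#' @param subject name of the participant identifier column.
#' @return data.frame of test results: one row per main effect and
#'   interaction (7 rows), columns as in [kruskal_wallis()] plus the error
#'   stratum in `note`.
#' @export
mixed_anova_3way <- function(table, dv = "mu",
                             within = c("delta_r_sign", "bin"),
                             between = "group",
                             subject = "participant_id") {
  stopifnot(is.data.frame(table),
            all(c(dv, within, between, subject) %in% names(table)))
  df <- table[, c(subject, between, within, dv)]
  names(df) <- c(".subj", ".btw", ".w1", ".w2", ".y")
  df$.subj <- factor(df$.subj)
  df$.btw <- factor(df$.btw)
  df$.w1 <- factor(df$.w1)
  df$.w2 <- factor(df$.w2)
  # listwise-complete participants only
  n_cells <- nlevels(df$.w1) * nlevels(df$.w2)
  ok <- !is.na(df$.y)
  cnt <- table(df$.subj[ok])
  keep <- names(cnt)[cnt == n_cells]
  dropped <- setdiff(levels(df$.subj), keep)
  if (length(dropped)) {
    message(sprintf("mixed_anova_3way: dropping %d participant(s) with incomplete cells",
                    length(dropped)))
  }
  df <- df[ok & df$.subj %in% keep, ]
  df$.subj <- droplevels(df$.subj)
  if (nlevels(df$.subj) < 3L) stop("too few complete participants")
  df$.btw <- droplevels(df$.btw)
  if (nlevels(df$.btw) < 2L) {
    stop("between factor has fewer than 2 levels among complete participants")
  }
  effects <- c(".btw", ".w1", ".btw:.w1", ".w2", ".btw:.w2", ".w1:.w2",
               ".btw:.w1:.w2")
  if (sd(df$.y) == 0) {
    # a constant response carries no effects at all
    out <- do.call(rbind, lapply(effects, function(e) {
      .test_result(e, 0, NA_real_, NA_real_, 1, note = "constant dv")
    }))
    map <- c(".btw" = between, ".w1" = within[1L], ".w2" = within[2L])
    for (nm in names(map)) out$effect <- gsub(nm, map[[nm]], out$effect,
                                              fixed = TRUE)
    return(out)
  }
  fit <- aov(.y ~ .btw * .w1 * .w2 + Error(.subj / (.w1 * .w2)), data = df)
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1L]]
    effs <- trimws(rownames(tab))
    for (i in seq_along(effs)) {
      if (effs[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- .test_result(
        effect = effs[i], statistic = tab[i, "F value"],
        df1 = tab[i, "Df"], df2 = tab[nrow(tab), "Df"],
        p = tab[i, "Pr(>F)"], note = stratum)
    }
  }
  out <- do.call(rbind, rows)
  map <- c(".btw" = between, ".w1" = within[1L], ".w2" = within[2L])
  for (nm in names(map)) out$effect <- gsub(nm, map[[nm]], out$effect,
                                            fixed = TRUE)
  rownames(out) <- NULL
  out
}

#' Dependent-sample (paired) t-test
#'
#' Two-sided paired t-test; a zero-variance difference vector is flagged as
#' degenerate rather than raising (t = 0, p = 1 when the difference is
#' identically zero).
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 3.
#' @param effect label for the result row.
#' @return one-row test-result data.frame; `note` is "degenerate" when the
#'   differences have zero variance.
#' @export
paired_t <- function(values_a, values_b, effect = "paired") {
  if (length(values_a) != length(values_b) || length(values_a) < 3L) {
    stop("paired samples must have equal length >= 3")
  }
  d <- values_a - values_b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(.test_result(effect, 0, n - 1, NA_real_, 1,
                          note = "degenerate"))
    }
    return(.test_result(effect, sign(mean(d)) * Inf, n - 1, NA_real_, 0,
                        note = "degenerate"))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  .test_result(effect, unname(tt$statistic), unname(tt$parameter),
               NA_real_, tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (clipped at 1) for one family of hypotheses.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Apply FDR control to a family of test results
#'
#' Fills the `p_fdr` and `family` columns of a test-result table, treating
#' all rows as one family.
#'
#' @param results data.frame as returned by the test functions.
#' @param family family identifier.
#' @return the table with `p_fdr` filled in.
#' @export
fdr_family <- function(results, family = "family1") {
  stopifnot(is.data.frame(results), "p" %in% names(results))
  results$p_fdr <- fdr_bh(results$p)
  results$family <- family
  results
}
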
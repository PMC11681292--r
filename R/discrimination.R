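#' Area under the ROC curve (rank-based, ties half-credited)
#'
#' Computes the AUROC as the Mann-Whitney probability that a randomly chosen
#' event outscores a randomly chosen non-event, with tied pairs receiving
#' half credit: `(concordant + 0.5 * tied) / (n_pos * n_neg)`. The rank-based
#' computation is exactly equal to exhaustive pair counting, and the result
#' is invariant under any strictly increasing transform of the scores.
#'
#' @param scores Numeric scores (higher means riskier).
#' @param labels Binary outcomes (0/1), same length; both classes required.
#' @return The AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.4, 0.5, 0.2, 0.4), c(1, 1, 0, 0, 0))
auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1L)
  n_neg <- length(labels) - n_pos
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with step interpolation: the sum over distinct score
#' cutoffs of the recall increment times the precision at that cutoff.
#' Reported for completeness only; it is strongly prevalence-dependent, so
#' cross-period stability testing uses the AUROC instead.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @export
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
auprc <- function(scores, labels) {
  labels <- check_binary_labels(labels, scores, both_classes = FALSE)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) {
    stop_shiftmon("input is degenerate: no positive cases.", "shiftmon_degenerate_error")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  # evaluate at the last index of each distinct score (tie groups collapse)
  last <- which(s != c(s[-1], NA) | cum_n == length(y))
  tp <- cum_tp[last]
  prec <- tp / cum_n[last]
  d_tp <- diff(c(0, tp))
  sum(d_tp * prec) / n_pos
}

#' Hanley-McNeil standard error of an AUROC
#'
#' Closed-form standard error of an estimated AUROC `A` from `n_pos` events
#' and `n_neg` non-events, using the exponential-model moments
#' `Q1 = A / (2 - A)` and `Q2 = 2 * A^2 / (1 + A)`:
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos * n_neg))`.
#'
#' @param auroc Estimated AUROC in `[0, 1]`.
#' @param n_pos,n_neg Event and non-event counts, each at least 1.
#' @return The standard error (0 when `auroc` is exactly 0 or 1).
#' @export
#' @examples
#' hanley_mcneil_se(0.8, n_pos = 50, n_neg = 100)
hanley_mcneil_se <- function(auroc, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) {
    stop_shiftmon("`n_pos` and `n_neg` must each be at least 1.", "shiftmon_input_error")
  }
  check_prob_vector(auroc, "auroc", open = FALSE)
  a <- auroc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  sqrt(pmax(v, 0))
}

#' Per-period ROC summary
#'
#' @param scores,labels As in [auroc()].
#' @param period Period label attached to the summary.
#' @return A one-row tibble: `period`, `n`, `n_pos`, `n_neg`, `incidence`,
#'   `auroc`, `se_auroc` (Hanley-McNeil), `auprc`.
#' @export
roc_summary <- function(scores, labels, period = NA_character_) {
  labels <- check_binary_labels(labels, scores)
  a <- auroc(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  tibble::tibble(
    period = as.character(period),
    n = length(labels),
    n_pos = n_pos,
    n_neg = n_neg,
    incidence = n_pos / length(labels),
    auroc = a,
    se_auroc = hanley_mcneil_se(a, n_pos, n_neg),
    auprc = auprc(scores, labels)
  )
}

#' Independent-samples Z-test comparing two AUROCs
#'
#' Tests the difference of two AUROCs estimated on disjoint samples (e.g.
#' different calendar years) using their Hanley-McNeil standard errors:
#' `Z = (A_a - A_b) / sqrt(SE_a^2 + SE_b^2)`, with a two-sided p-value from
#' the standard normal.
#'
#' @param a,b One-row [roc_summary()] tibbles (or lists with `period`,
#'   `auroc` and `se_auroc`).
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `period_a`, `period_b`, `delta_auroc`, `z`,
#'   `p_value`, `significant`.
#' @export
#' @examples
#' s1 <- roc_summary(runif(100), rbinom(100, 1, 0.3), "2020")
#' s2 <- roc_summary(runif(100), rbinom(100, 1, 0.3), "2021")
#' auroc_z_test(s1, s2)
auroc_z_test <- function(a, b, alpha = 0.05) {
  se <- sqrt(a$se_auroc^2 + b$se_auroc^2)
  d <- a$auroc - b$auroc
  if (se == 0) {
    if (d != 0) {
      stop_shiftmon("Z statistic undefined: both standard errors are zero but the AUROCs differ.",
                    "shiftmon_degenerate_error")
    }
    z <- 0
  } else {
    z <- d / se
  }
  p <- if (z == 0) 1 else 2 * pnorm(-abs(z))
  tibble::tibble(
    period_a = as.character(a$period), period_b = as.character(b$period),
    delta_auroc = d, z = z, p_value = p, significant = p < alpha
  )
}

#' Per-period discrimination metrics for a cohort
#'
#' Computes a [roc_summary()] for every per-period test split (the
#' calibration split is never included) and, optionally, all pairwise
#' AUROC Z-tests.
#'
#' @param cohort A `scored_cohort` or data frame of scored cases with
#'   `period`, `label`, `raw_score` and `split` columns.
#' @param score_col Which score column to evaluate (default `"raw_score"`).
#' @return A tibble with one [roc_summary()] row per period.
#' @export
discrimination_by_period <- function(cohort, score_col = "raw_score") {
  cases <- cohort_cases(cohort, split = "test")
  dplyr::bind_rows(lapply(unique(cases$period), function(p) {
    df <- cases[cases$period == p, , drop = FALSE]
    roc_summary(df[[score_col]], df$label, period = p)
  }))
}

#' All pairwise AUROC Z-tests between periods
#'
#' @param summaries A tibble of per-period [roc_summary()] rows.
#' @param alpha Significance level.
#' @return A tibble with one [auroc_z_test()] row per unordered period pair.
#' @export
pairwise_auroc_tests <- function(summaries, alpha = 0.05) {
  k <- nrow(summaries)
  if (k < 2) {
    stop_shiftmon("at least two period summaries are required.", "shiftmon_input_error")
  }
  pairs <- utils::combn(k, 2)
  dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    auroc_z_test(summaries[pairs[1, j], ], summaries[pairs[2, j], ], alpha = alpha)
  }))
}

#' Mean and population SD of yearly metric values
#'
#' Summarizes a set of per-year metric values (e.g. AUROC percentages) by
#' their arithmetic mean and population standard deviation (denominator `n`).
#'
#' @param values Numeric vector of at least 2 values.
#' @return A one-row tibble with `mean` and `sd` at full precision; see
#'   [format_mean_sd()] for the 2-decimal reporting convention.
#' @export
#' @examples
#' summarize_yearly(c(90.54, 90.40, 89.84, 90.69))
summarize_yearly <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values)) {
    stop_shiftmon("`values` must be numeric with at least 2 values.", "shiftmon_input_error")
  }
  m <- mean(values)
  tibble::tibble(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Format a yearly summary as "mean (SD)"
#'
#' Reporting convention for yearly summaries: the mean is rounded to
#' `digits` decimals and the population SD is truncated (rounded toward
#' zero) at `digits` decimals. Truncation, not rounding, is used for the SD
#' because tabulated metric values are themselves rounded: the SD computed
#' from full-precision values can only be smaller than the SD of their
#' rounded versions, so truncation reproduces summaries computed before
#' rounding while never overstating the spread.
#'
#' @param values Numeric vector of at least 2 values.
#' @param digits Decimal places (default 2).
#' @return A string such as `"90.37 (0.32)"`.
#' @export
#' @examples
#' format_mean_sd(c(90.54, 90.40, 89.84, 90.69))
format_mean_sd <- function(values, digits = 2) {
  s <- summarize_yearly(values)
  f <- 10^digits
  sprintf("%.*f (%.*f)", digits, round(s$mean, digits), digits,
          floor(s$sd * f) / f)
}
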
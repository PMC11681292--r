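#' Select an alert threshold balancing over- and underdiagnosis
#'
#' Scans every candidate threshold (the distinct calibrated probabilities
#' plus 0 and 1; the objective is piecewise constant between observed values,
#' so this grid is lossless) and returns the one minimizing
#' `|FNR - FPR|` — the absolute gap between the underdiagnosis rate (FNR)
#' and the overdiagnosis rate (FPR). Ties are broken toward the smallest
#' threshold. Intended to be run on a held-out calibration split with
#' already-calibrated probabilities.
#'
#' @param probs Calibrated probabilities.
#' @param labels Binary outcomes (0/1); both classes required.
#' @return The selected threshold probability.
#' @export
#' @examples
#' select_threshold(c(0.1, 0.2, 0.6, 0.7, 0.9), c(0, 0, 1, 0, 1))
select_threshold <- function(probs, labels) {
  check_prob_vector(probs, "probs", open = FALSE)
  labels <- check_binary_labels(labels, probs)
  cand <- sort(unique(c(0, probs, 1)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  # exact integer objective: |FNR - FPR| = |fn * n_neg - fp * n_pos| / (n_pos * n_neg),
  # so ties break to the smallest threshold without floating-point fuzz
  obj <- vapply(cand, function(t) {
    alert <- probs >= t
    fp <- sum(alert & labels == 0L)
    fn <- sum(!alert & labels == 1L)
    abs(fn * n_neg - fp * n_pos)
  }, numeric(1))
  cand[which.min(obj)]  # which.min takes the first, i.e. smallest threshold
}

#' Classify an alert outcome into five categories
#'
#' Extends the usual confusion categories with an onset-aware split of the
#' true positives: an alert shown at or after the condition's onset is
#' "arguably FN/TP" — diagnostic rather than predictive. Categories:
#' `TN` (control, no alert), `FP` (control, alert), `FN` (case, no alert),
#' `TP` (case, alert strictly before onset, or onset unknown),
#' `TP_AFTER_ONSET` (case, alert at/after onset). When onset times are
#' unavailable (as with discharge diagnosis codes, which carry no onset
#' information) `TP_AFTER_ONSET` cannot be assigned and an alert at any time
#' during the stay counts as `TP`; rate computations always collapse
#' `TP_AFTER_ONSET` into `TP`.
#'
#' @param label Binary outcome(s) (0/1).
#' @param alerted Logical: was an alert shown at any point?
#' @param onset_time Optional onset day offset (cases only; `NA` if unknown).
#' @param alert_time Optional day offset of the first alert.
#' @return A character vector over
#'   `c("TN", "FP", "FN", "TP", "TP_AFTER_ONSET")`.
#' @export
#' @examples
#' classify_alert(1, TRUE, onset_time = 5, alert_time = 2)  # "TP"
#' classify_alert(1, TRUE, onset_time = 5, alert_time = 6)  # "TP_AFTER_ONSET"
classify_alert <- function(label, alerted, onset_time = NA_real_,
                           alert_time = NA_real_) {
  n <- max(length(label), length(alerted), length(onset_time), length(alert_time))
  label <- rep_len(as.integer(label), n)
  alerted <- rep_len(as.logical(alerted), n)
  onset_time <- rep_len(as.numeric(onset_time), n)
  alert_time <- rep_len(as.numeric(alert_time), n)
  if (any(label == 0L & !is.na(onset_time))) {
    stop_shiftmon("inconsistent input: onset_time given for a control.",
                  "shiftmon_input_error")
  }
  if (any(alerted & !is.na(onset_time) & is.na(alert_time))) {
    stop_shiftmon("inconsistent input: alerted with known onset_time but no alert_time.",
                  "shiftmon_input_error")
  }
  out <- character(n)
  is_ctrl <- label == 0L
  out[is_ctrl & !alerted] <- "TN"
  out[is_ctrl & alerted] <- "FP"
  out[!is_ctrl & !alerted] <- "FN"
  before <- !is_ctrl & alerted & (is.na(onset_time) | alert_time < onset_time)
  out[before] <- "TP"
  out[!is_ctrl & alerted & !before] <- "TP_AFTER_ONSET"
  out
}

#' Confusion summary at an operating threshold
#'
#' Alerts are triggered when `prob >= threshold` (ties alert). Reports
#' counts and the monitoring rates: alert rate `(TP + FP) / N`,
#' overdiagnosis = FPR = `FP / (FP + TN)`, underdiagnosis = FNR =
#' `FN / (FN + TP)`.
#'
#' @param probs Probabilities.
#' @param labels Binary outcomes (0/1).
#' @param threshold Alert threshold in `[0, 1]`.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `fn`, `tn`, `n`,
#'   `alert_rate`, `fpr`, `fnr`.
#' @export
#' @examples
#' confusion_summary(c(0.9, 0.4, 0.5, 0.2, 0.4), c(1, 1, 0, 0, 0), 0.5)
confusion_summary <- function(probs, labels, threshold) {
  check_prob_vector(probs, "probs", open = FALSE)
  labels <- check_binary_labels(labels, probs, both_classes = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop_shiftmon("`threshold` must lie in [0, 1].", "shiftmon_input_error")
  }
  alert <- probs >= threshold
  tp <- sum(alert & labels == 1L)
  fp <- sum(alert & labels == 0L)
  fn <- sum(!alert & labels == 1L)
  tn <- sum(!alert & labels == 0L)
  n <- length(labels)
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    alert_rate = (tp + fp) / n,
    fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
    fnr = if (fn + tp > 0) fn / (fn + tp) else 0
  )
}

#' Net benefit of an alerting strategy
#'
#' `NB = TP/N - (FP/N) * p_t / (1 - p_t)`: true positives gained per patient,
#' discounting false positives by the odds of the threshold probability
#' `p_t` (the probability at which a clinician judges alerting and not
#' alerting to be of equal value).
#'
#' @param tp,fp True/false positive counts.
#' @param n Total number of predictions.
#' @param p_t Threshold probability in `[0, 1)`.
#' @return The net benefit (units: true positives per patient).
#' @export
#' @examples
#' net_benefit(tp = 10, fp = 20, n = 100, p_t = 0.2)  # 0.05
net_benefit <- function(tp, fp, n, p_t) {
  if (any(p_t < 0) || any(p_t >= 1)) {
    stop_shiftmon("`p_t` must lie in [0, 1) (the false-positive weight is undefined at 1).",
                  "shiftmon_input_error")
  }
  tp / n - (fp / n) * p_t / (1 - p_t)
}

#' Decision curve of a model against treat-all and treat-none
#'
#' Evaluates the model's net benefit over a grid of threshold probabilities
#' (alerting when `prob >= p_t`), together with the two reference
#' strategies: alerting every patient
#' (`nb_all = prevalence - (1 - prevalence) * p_t / (1 - p_t)`, which
#' crosses zero exactly at `p_t = prevalence`) and alerting no one
#' (`nb_none = 0`). At `p_t = 0` the model curve starts at the prevalence.
#'
#' @param probs Probabilities.
#' @param labels Binary outcomes (0/1).
#' @param thresholds Grid of threshold probabilities in `[0, 1)`.
#' @param period Optional period label column.
#' @return A tibble: `period`, `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0, 0.99, by = 0.01),
                           period = NA_character_) {
  if (length(thresholds) == 0) {
    stop_shiftmon("`thresholds` must be a nonempty grid in [0, 1).", "shiftmon_input_error")
  }
  if (any(thresholds < 0) || any(thresholds >= 1)) {
    stop_shiftmon("`thresholds` must lie in [0, 1).", "shiftmon_input_error")
  }
  labels <- check_binary_labels(labels, probs, both_classes = FALSE)
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(thresholds, function(t) {
    alert <- probs >= t
    net_benefit(sum(alert & labels == 1L), sum(alert & labels == 0L), n, t)
  }, numeric(1))
  tibble::tibble(
    period = as.character(period),
    threshold = thresholds,
    nb_model = nb_model,
    nb_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    nb_none = 0
  )
}

# replicates to add so (n_pos + k)/(n + k) is closest to target; tie -> smaller k
augment_k <- function(n_pos, n, target) {
  if (target >= 1) stop_shiftmon("`target` must be below 1.", "shiftmon_input_error")
  k_star <- (target * n - n_pos) / (1 - target)
  cand <- unique(pmax(c(floor(k_star), ceiling(k_star)), 0))
  gap <- abs((n_pos + cand) / (n + cand) - target)
  cand[order(gap, cand)][1]
}

#' Standardize incidence across periods by augmenting positives
#'
#' Decision curves start (at `p_t = 0`) at the prevalence, so curves from
#' periods with different incidences are not directly comparable. This
#' raises every lower-incidence per-period test split to the maximum period
#' incidence by appending duplicates of its positive cases (sampled with
#' replacement); the number added minimizes the absolute gap to the target
#' incidence (ties toward fewer duplicates). Existing cases are never
#' modified or removed; duplicated rows get a `#dup<i>` suffix on `case_id`.
#'
#' @param cohort A `scored_cohort`.
#' @param seed Integer RNG seed for the duplicate draw.
#' @return A `scored_cohort` whose test splits share a common incidence (to
#'   the closest achievable value).
#' @export
standardize_incidence <- function(cohort, seed = 1L) {
  cases <- cohort_cases(cohort)
  test <- cases[cases$split == "test", , drop = FALSE]
  periods <- unique(test$period)
  if (length(periods) < 2) {
    stop_shiftmon("at least 2 periods are required to standardize incidence.",
                  "shiftmon_input_error")
  }
  inc <- vapply(split(test$label, test$period), mean, numeric(1))
  if (any(inc == 0)) {
    stop_shiftmon("a period has no positive cases: cannot augment incidence from nothing.",
                  "shiftmon_degenerate_error")
  }
  target <- max(inc)
  with_seed(seed, {
    added <- lapply(periods, function(p) {
      df <- test[test$period == p, , drop = FALSE]
      k <- augment_k(sum(df$label == 1L), nrow(df), target)
      if (k == 0) return(NULL)
      pos <- df[df$label == 1L, , drop = FALSE]
      dup <- pos[sample.int(nrow(pos), k, replace = TRUE), , drop = FALSE]
      dup$case_id <- sprintf("%s#dup%d", dup$case_id, seq_len(k))
      dup
    })
    new_scored_cohort(dplyr::bind_rows(cases, dplyr::bind_rows(added)),
                      cohort$config)
  })
}

#' Nonparametric bootstrap comparison of two decision curves
#'
#' Resamples cases with replacement within each of two independent splits
#' (unpaired bootstrap) and, at each threshold of interest, computes the
#' replicate distribution of the net-benefit difference
#' `dNB = NB_a - NB_b`. The two-sided p-value is
#' `2 * min(P(dNB <= 0), P(dNB >= 0))`, clipped to `[0, 1]`. No multiplicity
#' correction is applied across thresholds by default.
#'
#' @param split_a,split_b Data frames with `prob` and `label` columns (or
#'   lists with `probs`/`labels`).
#' @param thresholds_of_interest Threshold probabilities to test; the
#'   default covers the low range most relevant to clinical alerting.
#' @param n_boot Bootstrap replicates (at least 100).
#' @param seed Integer RNG seed.
#' @param p_adjust_method Optional multiplicity correction passed to
#'   [stats::p.adjust()]; `"none"` (default) matches per-threshold reporting.
#' @return A tibble: `threshold`, `nb_a`, `nb_b`, `delta_nb`, `p_value`.
#' @export
compare_decision_curves <- function(split_a, split_b,
                                    thresholds_of_interest =
                                      c(0.01, 0.02, 0.05, 0.10, 0.15, 0.20),
                                    n_boot = 2000L, seed = 1L,
                                    p_adjust_method = "none") {
  if (n_boot < 100) {
    stop_shiftmon("`n_boot` must be at least 100.", "shiftmon_input_error")
  }
  as_pl <- function(s, nm) {
    if (is.data.frame(s)) {
      list(probs = s$prob, labels = check_binary_labels(s$label))
    } else {
      list(probs = s$probs, labels = check_binary_labels(s$labels))
    }
  }
  a <- as_pl(split_a, "split_a")
  b <- as_pl(split_b, "split_b")
  for (s in list(a, b)) {
    if (sum(s$labels == 1L) == 0 || sum(s$labels == 0L) == 0) {
      stop_shiftmon("both splits must contain both classes.", "shiftmon_degenerate_error")
    }
  }
  tt <- thresholds_of_interest
  if (any(tt < 0) || any(tt >= 1)) {
    stop_shiftmon("`thresholds_of_interest` must lie in [0, 1).", "shiftmon_input_error")
  }
  w <- tt / (1 - tt)
  # NB per bootstrap replicate via multinomial case weights: for weights W
  # (n x n_boot) and per-case indicators X (n x K), counts are t(W) %*% X
  boot_nb <- function(s) {
    n <- length(s$labels)
    x_tp <- outer(s$probs, tt, ">=") * (s$labels == 1L)
    x_fp <- outer(s$probs, tt, ">=") * (s$labels == 0L)
    wts <- rmultinom(n_boot, size = n, prob = rep.int(1, n))
    tp <- crossprod(wts, x_tp)
    fp <- crossprod(wts, x_fp)
    tp / n - sweep(fp / n, 2, w, "*")  # n_boot x K matrix of net benefits
  }
  with_seed(seed, {
    nb_boot_a <- boot_nb(a)
    nb_boot_b <- boot_nb(b)
  })
  delta <- nb_boot_a - nb_boot_b
  p <- vapply(seq_along(tt), function(j) {
    d <- delta[, j]
    min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  }, numeric(1))
  p <- stats::p.adjust(p, method = p_adjust_method)
  point_nb <- function(s, t) {
    alert <- s$probs >= t
    net_benefit(sum(alert & s$labels == 1L), sum(alert & s$labels == 0L),
                length(s$labels), t)
  }
  tibble::tibble(
    threshold = tt,
    nb_a = vapply(tt, function(t) point_nb(a, t), numeric(1)),
    nb_b = vapply(tt, function(t) point_nb(b, t), numeric(1)),
    delta_nb = vapply(tt, function(t) point_nb(a, t) - point_nb(b, t), numeric(1)),
    p_value = p
  )
}
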
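#' Fit a Platt scaling recalibration model
#'
#' Maximum-likelihood fit of the two-parameter logistic recalibration
#' `calibrated = 1 / (1 + exp(A * f + B))` where `f = qlogis(raw_score)`,
#' following the original Platt sign convention: `(A, B) = (-1, 0)` is the
#' identity mapping, and any score distorted by a logit-affine map is exactly
#' recovered within this family. Fitted by Newton-Raphson on the negative
#' log-likelihood until the gradient norm falls below `tol`. Platt's
#' out-of-sample target smoothing (`(N+ + 1)/(N+ + 2)` for events,
#' `1/(N- + 2)` for non-events) is available but off by default.
#'
#' The model must be fitted on a held-out calibration split, never on the
#' test periods it will be used to assess.
#'
#' @param raw_scores Raw model probabilities in (0, 1).
#' @param labels Binary outcomes (0/1); both classes required, `n >= 20`.
#' @param smoothing Use Platt's smoothed targets (default `FALSE`).
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return A `platt_model`: list with `A`, `B`, `n_fit`, `converged`,
#'   `iterations`.
#' @export
#' @examples
#' set.seed(1)
#' p <- runif(200, 0.05, 0.95)
#' y <- rbinom(200, 1, p)
#' fit_platt(p, y)
fit_platt <- function(raw_scores, labels, smoothing = FALSE,
                      max_iter = 100L, tol = 1e-8) {
  check_prob_vector(raw_scores, "raw_scores")
  labels <- check_binary_labels(labels, raw_scores)
  n <- length(labels)
  if (n < 20) {
    stop_shiftmon("at least 20 cases are required to fit Platt scaling.",
                  "shiftmon_input_error")
  }
  f <- qlogis(raw_scores)
  t <- as.numeric(labels)
  if (isTRUE(smoothing)) {
    n_pos <- sum(labels == 1L)
    n_neg <- n - n_pos
    t <- ifelse(labels == 1L, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  }
  theta <- c(A = -1, B = 0)  # identity start
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    p <- plogis(-(theta[1] * f + theta[2]))
    # d eta / d theta = (-f, -1) with eta = -(A f + B)
    g <- c(sum((p - t) * (-f)), sum(p - t) * -1)
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-12)
    h11 <- sum(w * f^2)
    h12 <- sum(w * f)
    h22 <- sum(w)
    det <- h11 * h22 - h12^2
    if (!is.finite(det) || det <= 0) break
    step <- c(h22 * g[1] - h12 * g[2], -h12 * g[1] + h11 * g[2]) / det
    theta <- theta - step
  }
  if (!converged) {
    p <- plogis(-(theta[1] * f + theta[2]))
    g <- c(sum((p - t) * (-f)), sum(p - t) * -1)
    converged <- sqrt(sum(g^2)) < tol
    if (!converged) {
      stop_shiftmon(sprintf("Platt fit did not converge in %d iterations.", max_iter),
                    "shiftmon_convergence_error")
    }
  }
  structure(list(A = unname(theta[1]), B = unname(theta[2]),
                 n_fit = n, converged = converged, iterations = it,
                 smoothing = isTRUE(smoothing)),
            class = "platt_model")
}

#' @export
print.platt_model <- function(x, ...) {
  cat(sprintf("<platt_model> calibrated = 1/(1 + exp(%.4f * logit(raw) + %.4f))\n",
              x$A, x$B))
  cat(sprintf("  fitted on %d cases in %d Newton step(s)%s\n", x$n_fit,
              x$iterations, if (x$smoothing) " (smoothed targets)" else ""))
  invisible(x)
}

#' Apply a fitted Platt model to raw scores
#'
#' Elementwise `1 / (1 + exp(A * qlogis(raw) + B))`. For the usual `A < 0`
#' the mapping is strictly increasing, so the AUROC of the calibrated scores
#' is exactly the AUROC of the raw scores: recalibration changes calibration,
#' never discrimination.
#'
#' @param model A `platt_model` from [fit_platt()].
#' @param raw_scores Raw probabilities in (0, 1).
#' @return Calibrated probabilities.
#' @export
apply_platt <- function(model, raw_scores) {
  stopifnot(inherits(model, "platt_model"))
  check_prob_vector(raw_scores, "raw_scores")
  plogis(-(model$A * qlogis(raw_scores) + model$B))
}

# deterministic quantile bin assignment: stable sort by prob (ties keep input
# order), contiguous bins whose sizes differ by at most one
quantile_bins <- function(probs, n_bins) {
  n <- length(probs)
  if (n < n_bins) {
    stop_shiftmon(sprintf("need at least `n_bins` = %d cases, got %d.", n_bins, n),
                  "shiftmon_input_error")
  }
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(probs)  # radix: stable for ties
  bin_of_sorted <- rep.int(seq_len(n_bins), sizes)
  bin <- integer(n)
  bin[ord] <- bin_of_sorted
  bin
}

#' Quantile-binned reliability curve
#'
#' Sorts cases by predicted probability and splits them into `n_bins`
#' contiguous bins of (near-)equal size, so no bin is starved of cases. Each
#' bin reports the mean predicted probability, the observed event rate, and a
#' Wilson 95% CI on the observed rate.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcomes (0/1).
#' @param n_bins Number of quantile bins (default 10).
#' @param conf Confidence level for the Wilson interval.
#' @return A tibble with one row per bin: `bin`, `n`, `mean_pred`,
#'   `observed`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' set.seed(1)
#' p <- runif(500)
#' reliability_curve(p, rbinom(500, 1, p), n_bins = 5)
reliability_curve <- function(probs, labels, n_bins = 10, conf = 0.95) {
  check_prob_vector(probs, "probs", open = FALSE)
  labels <- check_binary_labels(labels, probs, both_classes = FALSE)
  bin <- quantile_bins(probs, n_bins)
  dplyr::bind_rows(lapply(seq_len(n_bins), function(b) {
    in_b <- bin == b
    nb <- sum(in_b)
    obs <- mean(labels[in_b])
    ci <- wilson_ci(sum(labels[in_b]), nb, conf)
    tibble::tibble(bin = b, n = nb, mean_pred = mean(probs[in_b]),
                   observed = obs, ci_low = ci[["low"]], ci_high = ci[["high"]])
  }))
}

#' Expected and maximum calibration error
#'
#' On the same quantile bins as [reliability_curve()]:
#' `ECE = sum_b (n_b / n) * |mean_pred_b - observed_b|` (count-weighted mean
#' absolute gap) and `MCE = max_b |mean_pred_b - observed_b|`. Larger values
#' mean greater miscalibration; `ECE <= MCE` always.
#'
#' @inheritParams reliability_curve
#' @return A one-row tibble with `ece` and `mce`.
#' @export
calibration_errors <- function(probs, labels, n_bins = 10) {
  curve <- reliability_curve(probs, labels, n_bins = n_bins)
  gap <- abs(curve$mean_pred - curve$observed)
  tibble::tibble(ece = sum(curve$n * gap) / sum(curve$n), mce = max(gap))
}

#' Per-period calibration-shift report
#'
#' For every per-period test split of a cohort, builds reliability curves and
#' ECE/MCE both for the raw scores and for Platt-calibrated scores (model
#' fitted on the calibration split unless supplied). A period is flagged as
#' calibration-shifted when its post-calibration ECE exceeds the calibration
#' split's own post-calibration ECE by more than `margin` (absolute, default
#' 0.05): the calibration split is the in-sample reference of what "still
#' calibrated" looks like, so only drift beyond it raises the flag.
#'
#' @param cohort A `scored_cohort` (or data frame of scored cases with a
#'   `split` column).
#' @param platt Optional pre-fitted [fit_platt()] model; fitted on the
#'   cohort's calibration split when `NULL`.
#' @param n_bins Quantile bins for curves and errors.
#' @param margin Absolute ECE margin above the reference before a period is
#'   flagged.
#' @return A `calibration_report`: list with `curves` (tibble: `period`,
#'   `phase` raw/calibrated, bin rows), `errors` (tibble: `period`, `phase`,
#'   `ece`, `mce`), `reference_ece` (calibration split, post-calibration),
#'   `flags` (tibble: `period`, `ece_calibrated`, `shift_flag`), `platt`,
#'   `margin`, `n_bins`.
#' @export
calibration_shift_report <- function(cohort, platt = NULL, n_bins = 10,
                                     margin = 0.05) {
  calib <- cohort_cases(cohort, split = "calibration")
  test <- cohort_cases(cohort, split = "test")
  if (is.null(platt)) {
    platt <- fit_platt(calib$raw_score, calib$label)
  }
  stopifnot(inherits(platt, "platt_model"))
  eval_split <- function(df, period_label) {
    cal_scores <- apply_platt(platt, df$raw_score)
    phases <- list(raw = df$raw_score, calibrated = cal_scores)
    curves <- dplyr::bind_rows(lapply(names(phases), function(ph) {
      dplyr::mutate(reliability_curve(phases[[ph]], df$label, n_bins = n_bins),
                    period = period_label, phase = ph, .before = 1)
    }))
    errors <- dplyr::bind_rows(lapply(names(phases), function(ph) {
      dplyr::mutate(calibration_errors(phases[[ph]], df$label, n_bins = n_bins),
                    period = period_label, phase = ph, .before = 1)
    }))
    list(curves = curves, errors = errors)
  }
  ref <- eval_split(calib, "calibration")
  reference_ece <- ref$errors$ece[ref$errors$phase == "calibrated"]
  per_period <- lapply(unique(test$period), function(p) {
    eval_split(test[test$period == p, , drop = FALSE], p)
  })
  errors <- dplyr::bind_rows(ref$errors, dplyr::bind_rows(lapply(per_period, `[[`, "errors")))
  curves <- dplyr::bind_rows(ref$curves, dplyr::bind_rows(lapply(per_period, `[[`, "curves")))
  post <- errors[errors$phase == "calibrated" & errors$period != "calibration", ]
  flags <- tibble::tibble(
    period = post$period,
    ece_calibrated = post$ece,
    shift_flag = post$ece > reference_ece + margin
  )
  structure(list(curves = curves, errors = errors,
                 reference_ece = reference_ece, flags = flags,
                 platt = platt, margin = margin, n_bins = n_bins),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d period(s), %d quantile bins, margin %.3f\n",
              nrow(x$flags), x$n_bins, x$margin))
  cat(sprintf("  reference (calibration split) post-calibration ECE: %.4f\n",
              x$reference_ece))
  print(x$flags)
  invisible(x)
}
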
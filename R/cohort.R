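#' Configuration for a synthetic scored cohort
#'
#' Defines per-period cohorts of model-scored medical cases under an
#' equal-variance binormal latent-score model. Each case's binary outcome is
#' drawn with the period's incidence; a latent score `z` is drawn from
#' `Normal(mu_pos, sigma)` for cases and `Normal(mu_neg, sigma)` for controls;
#' the honest posterior probability `true_prob = P(label = 1 | z)` is then an
#' exactly logistic function of `z`. The raw model output is a distorted
#' version of that posterior, `raw_score = plogis(miscal_slope *
#' qlogis(true_prob) + miscal_offset)`, so that `miscal_slope = 1,
#' miscal_offset = 0` yields a perfectly calibrated score and any injected
#' logit-affine miscalibration is exactly recoverable by Platt scaling.
#'
#' @param periods Ordered character vector of period labels (e.g. calendar
#'   years).
#' @param n_per_period Cases per period (single value or one per period),
#'   each at least 20.
#' @param incidence Event probability per period, strictly in (0, 1); single
#'   value or one per period.
#' @param mu_pos,mu_neg Latent means for cases and controls.
#' @param sigma Common latent standard deviation, > 0.
#' @param miscal_slope,miscal_offset Per-period calibration distortion applied
#'   on the logit of `true_prob`; `1, 0` leaves the score perfectly
#'   calibrated. Single values or one per period (per-period values inject
#'   calibration drift).
#' @param calib_fraction Fraction of the earliest period's cases reserved
#'   (uniformly at random) for the calibration/threshold-selection split, in
#'   (0, 0.5]. The reserve is drawn from the earliest period only, mirroring
#'   a held-out share of the development data: recalibration and threshold
#'   selection must rest on pre-deployment data, untouched by any drift
#'   injected into later periods.
#' @param simulate_onset If `TRUE`, draw a length of stay (uniform 1..30
#'   days) for every case and, for events, an onset time uniform on
#'   `[0, los]`; used only by the five-category alert classifier.
#' @param seed Integer RNG seed; identical configuration and seed give a
#'   bit-identical cohort.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [expected_auroc()]
#' @export
#' @examples
#' cfg <- cohort_config(periods = c("2020", "2021"), n_per_period = 500,
#'                      incidence = 0.1, seed = 1)
#' cfg
cohort_config <- function(periods,
                          n_per_period,
                          incidence,
                          mu_pos = 1,
                          mu_neg = -1,
                          sigma = 1,
                          miscal_slope = 1,
                          miscal_offset = 0,
                          calib_fraction = 0.1,
                          simulate_onset = FALSE,
                          seed = 1L) {
  periods <- as.character(periods)
  k <- length(periods)
  cfg_err <- function(field, why) {
    stop_shiftmon(sprintf("invalid cohort configuration: `%s` %s.", field, why),
                  "shiftmon_config_error")
  }
  if (k < 1 || anyDuplicated(periods)) cfg_err("periods", "must be nonempty and unique")
  recycle <- function(x, field) {
    if (length(x) == 1) x <- rep(x, k)
    if (length(x) != k) cfg_err(field, "must have length 1 or one value per period")
    x
  }
  n_per_period <- recycle(as.integer(n_per_period), "n_per_period")
  if (any(n_per_period < 20)) cfg_err("n_per_period", "must be at least 20")
  incidence <- recycle(incidence, "incidence")
  if (any(incidence <= 0 | incidence >= 1)) cfg_err("incidence", "must be strictly in (0, 1)")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) cfg_err("sigma", "must be a single value > 0")
  miscal_slope <- recycle(miscal_slope, "miscal_slope")
  if (any(miscal_slope <= 0)) cfg_err("miscal_slope", "must be positive")
  miscal_offset <- recycle(miscal_offset, "miscal_offset")
  if (!is.numeric(calib_fraction) || length(calib_fraction) != 1 ||
      calib_fraction <= 0 || calib_fraction > 0.5) {
    cfg_err("calib_fraction", "must lie in (0, 0.5]")
  }
  structure(
    list(periods = periods, n_per_period = n_per_period, incidence = incidence,
         mu_pos = mu_pos, mu_neg = mu_neg, sigma = sigma,
         miscal_slope = miscal_slope, miscal_offset = miscal_offset,
         calib_fraction = calib_fraction,
         simulate_onset = isTRUE(simulate_onset), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  periods:      ", paste(x$periods, collapse = ", "), "\n")
  cat("  n per period: ", paste(x$n_per_period, collapse = ", "), "\n")
  cat("  incidence:    ", paste(format(x$incidence), collapse = ", "), "\n")
  cat(sprintf("  latent model:  Normal(%g, %g) vs Normal(%g, %g)  [expected AUROC %.4f]\n",
              x$mu_pos, x$sigma, x$mu_neg, x$sigma, expected_auroc(x)))
  cat("  miscal slope: ", paste(format(x$miscal_slope), collapse = ", "), "\n")
  cat("  miscal offset:", paste(format(x$miscal_offset), collapse = ", "), "\n")
  cat(sprintf("  calib fraction: %g   seed: %d\n", x$calib_fraction, x$seed))
  invisible(x)
}

#' Closed-form AUROC of the binormal latent model
#'
#' Under the equal-variance binormal model the AUROC of any strictly
#' increasing function of the latent score is
#' `pnorm((mu_pos - mu_neg) / (sigma * sqrt(2)))`; this serves as the analytic
#' oracle for the simulator.
#'
#' @param config A [cohort_config()].
#' @return The population AUROC in `[0, 1]`.
#' @export
#' @examples
#' expected_auroc(cohort_config("y", 100, 0.1, mu_pos = 1, mu_neg = -1))
expected_auroc <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pnorm((config$mu_pos - config$mu_neg) / (config$sigma * sqrt(2)))
}

new_scored_cohort <- function(cases, config = NULL) {
  structure(list(cases = cases, config = config), class = "scored_cohort")
}

#' Generate a synthetic scored cohort
#'
#' Draws the per-period cases described by a [cohort_config()]: Bernoulli
#' outcomes at the period incidence, binormal latent scores, the exact
#' logistic Bayes posterior as `true_prob`, and a logit-affine distorted
#' `raw_score`. A fraction `calib_fraction` of the earliest period's cases
#' (drawn uniformly at random) is assigned to the calibration split; all
#' remaining cases form per-period test splits. Fully deterministic given
#' the configuration (which includes the seed).
#'
#' @param config A [cohort_config()].
#' @return A `scored_cohort`: a list with `cases` (a tibble with columns
#'   `case_id`, `period`, `label`, `raw_score`, `true_prob`, `onset_time`,
#'   `los`, `split`) and the generating `config`.
#' @export
#' @examples
#' ch <- generate_cohort(cohort_config(c("2020", "2021"), 200, 0.15, seed = 7))
#' ch
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    parts <- lapply(seq_along(config$periods), function(i) {
      n <- config$n_per_period[i]
      pi_y <- config$incidence[i]
      label <- rbinom(n, 1L, pi_y)
      mu <- ifelse(label == 1L, config$mu_pos, config$mu_neg)
      z <- rnorm(n, mean = mu, sd = config$sigma)
      # Bayes posterior: logistic in z under the equal-variance binormal model
      slope <- (config$mu_pos - config$mu_neg) / config$sigma^2
      centre <- (config$mu_pos + config$mu_neg) / 2
      true_prob <- plogis(slope * (z - centre) + qlogis(pi_y))
      raw_score <- plogis(config$miscal_slope[i] * qlogis(true_prob) +
                            config$miscal_offset[i])
      los <- rep(NA_real_, n)
      onset <- rep(NA_real_, n)
      if (config$simulate_onset) {
        los <- as.numeric(sample.int(30L, n, replace = TRUE))
        is_case <- label == 1L
        onset[is_case] <- runif(sum(is_case), 0, los[is_case])
      }
      tibble::tibble(
        case_id = sprintf("%s-%06d", config$periods[i], seq_len(n)),
        period = config$periods[i],
        label = as.integer(label),
        raw_score = raw_score,
        true_prob = true_prob,
        onset_time = onset,
        los = los
      )
    })
    cases <- dplyr::bind_rows(parts)
    # the calibration reserve emulates the held-out share of the development
    # data: it is drawn uniformly at random from the earliest period only, so
    # that drift injected into later periods can never contaminate the
    # recalibration fit it is meant to expose
    cases$split <- "test"
    first <- cases$period == config$periods[1]
    cases$split[first] <- ifelse(runif(sum(first)) < config$calib_fraction,
                                 "calibration", "test")
    if (!any(cases$split == "calibration")) {
      stop_shiftmon("calibration split is empty; increase `calib_fraction` or `n_per_period`.",
                    "shiftmon_split_error")
    }
    empty <- setdiff(config$periods, unique(cases$period[cases$split == "test"]))
    if (length(empty) > 0) {
      stop_shiftmon(sprintf("test split empty for period(s): %s.",
                            paste(empty, collapse = ", ")),
                    "shiftmon_split_error")
    }
    new_scored_cohort(cases, config)
  })
}

#' @export
print.scored_cohort <- function(x, ...) {
  cases <- x$cases
  cat(sprintf("<scored_cohort> %d cases, %d period(s), %d in calibration split\n",
              nrow(cases), length(unique(cases$period)),
              sum(cases$split == "calibration")))
  prof <- dplyr::summarise(dplyr::group_by(cases, .data$period),
                           n = dplyr::n(),
                           incidence = mean(.data$label),
                           .groups = "drop")
  print(prof)
  invisible(x)
}

#' Extract cases from a cohort
#'
#' @param cohort A `scored_cohort` or a data frame of scored cases.
#' @param split `NULL` for all cases, `"calibration"` or `"test"`.
#' @param period Optional period label filter.
#' @return A tibble of scored cases.
#' @export
cohort_cases <- function(cohort, split = NULL, period = NULL) {
  cases <- if (inherits(cohort, "scored_cohort")) cohort$cases else tibble::as_tibble(cohort)
  if (!is.null(split)) cases <- cases[cases$split == split, , drop = FALSE]
  if (!is.null(period)) cases <- cases[cases$period %in% period, , drop = FALSE]
  cases
}

# apply fn(group_df) -> group_df to calibration split and each per-period test
# split independently, preserving the original split structure
map_splits <- function(cohort, fn) {
  cases <- cohort$cases
  calib <- cases[cases$split == "calibration", , drop = FALSE]
  test <- cases[cases$split == "test", , drop = FALSE]
  out <- list(fn(calib))
  for (p in unique(test$period)) {
    out <- c(out, list(fn(test[test$period == p, , drop = FALSE])))
  }
  new_scored_cohort(dplyr::bind_rows(out), cohort$config)
}

#' Downsample every split of a cohort
#'
#' Each per-period test split and the calibration split are independently
#' subsampled without replacement, label-agnostically, to
#' `round(fraction * n)` cases. Retained cases are unmodified. Used to probe
#' whether apparent calibration shifts are artifacts of data scale.
#'
#' @param cohort A `scored_cohort`.
#' @param fraction Retained fraction in (0, 1].
#' @param seed Integer RNG seed.
#' @return A `scored_cohort` with reduced splits.
#' @export
downsample_cohort <- function(cohort, fraction, seed = 1L) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stop_shiftmon("`fraction` must lie in (0, 1].", "shiftmon_input_error")
  }
  if (fraction == 1) return(cohort)
  with_seed(seed, {
    map_splits(cohort, function(df) {
      keep <- round(fraction * nrow(df))
      if (keep < 1) {
        stop_shiftmon("downsampling would empty a split.", "shiftmon_split_error")
      }
      df[sort(sample.int(nrow(df), keep)), , drop = FALSE]
    })
  })
}

# positive count minimizing |k/(k+n_neg) - target|; ties favour the smaller k
thin_k <- function(n_pos, n_neg, target) {
  k_star <- target * n_neg / (1 - target)
  cand <- unique(pmin(pmax(c(floor(k_star), ceiling(k_star)), 0), n_pos))
  gap <- abs(cand / (cand + n_neg) - target)
  cand[order(gap, cand)][1]
}

#' Thin a cohort's incidence by removing positive cases
#'
#' Randomly removes events from the calibration split and from every
#' per-period test split until each split's incidence is as close as possible
#' to `target_incidence` (the retained positive count `k` minimizes
#' `|k / (k + n_neg) - target|`). Negatives and all retained case fields are
#' untouched. Emulates artificially lowering a condition's incidence rate to
#' match a rarer condition.
#'
#' @param cohort A `scored_cohort`.
#' @param target_incidence Target incidence, strictly below the current
#'   incidence of every affected split.
#' @param seed Integer RNG seed.
#' @return A `scored_cohort` with thinned splits.
#' @export
thin_incidence <- function(cohort, target_incidence, seed = 1L) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(target_incidence) || length(target_incidence) != 1 ||
      target_incidence <= 0 || target_incidence >= 1) {
    stop_shiftmon("`target_incidence` must lie in (0, 1).", "shiftmon_input_error")
  }
  cs <- cohort$cases
  test <- cs[cs$split == "test", , drop = FALSE]
  inc <- c(mean(cs$label[cs$split == "calibration"]),
           vapply(split(test$label, test$period), mean, numeric(1)))
  if (any(target_incidence >= inc)) {
    stop_shiftmon(
      "`target_incidence` must be below the current incidence of every split (thinning only removes events).",
      "shiftmon_target_error")
  }
  with_seed(seed, {
    map_splits(cohort, function(df) {
      pos <- which(df$label == 1L)
      n_neg <- nrow(df) - length(pos)
      k <- thin_k(length(pos), n_neg, target_incidence)
      drop <- if (k < length(pos)) sample(pos, length(pos) - k) else integer(0)
      if (length(drop) > 0) df <- df[-drop, , drop = FALSE]
      df
    })
  })
}

#' Read and write scored-cases tables
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `case_id,period,label,raw_score,true_prob,onset_time,los,split` and empty
#' fields for missing optionals.
#'
#' @param cohort A `scored_cohort` or tibble of cases.
#' @param path File path.
#' @return `read_scored_cases()` returns a `scored_cohort`;
#'   `write_scored_cases()` returns `path` invisibly.
#' @export
write_scored_cases <- function(cohort, path) {
  cases <- cohort_cases(cohort)
  cols <- c("case_id", "period", "label", "raw_score", "true_prob",
            "onset_time", "los", "split")
  for (m in setdiff(cols, names(cases))) cases[[m]] <- NA
  readr::write_csv(cases[cols], path, na = "")
  invisible(path)
}

#' @rdname write_scored_cases
#' @export
read_scored_cases <- function(path) {
  cases <- readr::read_csv(
    path,
    col_types = readr::cols(
      case_id = readr::col_character(),
      period = readr::col_character(),
      label = readr::col_integer(),
      raw_score = readr::col_double(),
      true_prob = readr::col_double(),
      onset_time = readr::col_double(),
      los = readr::col_double(),
      split = readr::col_character()
    )
  )
  bad <- which(!(cases$label %in% c(0L, 1L)) |
                 is.na(cases$raw_score) | cases$raw_score <= 0 | cases$raw_score >= 1)
  if (length(bad) > 0) {
    stop_shiftmon(sprintf("unparseable scored-case rows (data line %s): label must be 0/1 and raw_score in (0,1).",
                          paste(head(bad, 5), collapse = ", ")),
                  "shiftmon_parse_error")
  }
  new_scored_cohort(cases, config = NULL)
}
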
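test_that("configuration validation names the offending field", {
  expect_error(cohort_config("a", 10, 0.1), "n_per_period",
               class = "shiftmon_config_error")
  expect_error(cohort_config("a", 100, 1.2), "incidence",
               class = "shiftmon_config_error")
  expect_error(cohort_config("a", 100, 0.1, sigma = 0), "sigma",
               class = "shiftmon_config_error")
  expect_error(cohort_config("a", 100, 0.1, calib_fraction = 0.7),
               "calib_fraction", class = "shiftmon_config_error")
  expect_error(cohort_config(c("a", "a"), 100, 0.1), "periods",
               class = "shiftmon_config_error")
})

test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(c("x", "y"), 200, c(0.1, 0.2), seed = 99,
                       simulate_onset = TRUE)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cases, b$cases)
  # and the RNG state of the caller is untouched
  set.seed(5)
  before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("empirical incidence and AUROC match the generator's ground truth", {
  cfg <- cohort_config("y", 50000, 0.15, mu_pos = 1, mu_neg = -1, sigma = 1,
                       seed = 3)
  ch <- generate_cohort(cfg)
  cases <- cohort_cases(ch)
  pi_y <- 0.15
  expect_lt(abs(mean(cases$label) - pi_y),
            3 * sqrt(pi_y * (1 - pi_y) / nrow(cases)))
  # binormal closed form: pnorm(2 / sqrt(2)) = 0.9214
  expect_equal(expected_auroc(cfg), 0.9213504, tolerance = 1e-6)
  expect_lt(abs(auroc(cases$raw_score, cases$label) - expected_auroc(cfg)), 0.01)
  # cross-check the empirical AUROC by exhaustive pair counting on a subsample
  sub <- cases[sample.int(nrow(cases), 300), ]
  expect_equal(auroc(sub$raw_score, sub$label),
               pair_count_auroc(sub$raw_score, sub$label))
})

test_that("true_prob is the honest posterior: calibrated scores have vanishing ECE", {
  ch <- generate_cohort(cohort_config("y", 100000, 0.2, seed = 8))
  cases <- cohort_cases(ch)
  expect_lt(calibration_errors(cases$raw_score, cases$label, n_bins = 10)$ece,
            0.02)
  # with no injected distortion raw_score equals true_prob
  expect_equal(cases$raw_score, cases$true_prob)
})

test_that("miscalibration distorts raw_score on the logit scale only", {
  cfg <- cohort_config("y", 1000, 0.2, miscal_slope = 1.5, miscal_offset = 0.7,
                       seed = 4)
  cases <- cohort_cases(generate_cohort(cfg))
  expect_equal(qlogis(cases$raw_score),
               1.5 * qlogis(cases$true_prob) + 0.7, tolerance = 1e-12)
})

test_that("onset times exist only for cases and never exceed the stay", {
  cases <- cohort_cases(generate_cohort(
    cohort_config("y", 2000, 0.3, simulate_onset = TRUE, seed = 2)))
  expect_true(all(is.na(cases$onset_time[cases$label == 0])))
  has_onset <- !is.na(cases$onset_time)
  expect_true(all(cases$label[has_onset] == 1))
  expect_true(all(cases$onset_time[has_onset] <= cases$los[has_onset]))
})

test_that("downsampling subsamples each split to round(fraction * n) unchanged", {
  ch <- small_cohort(n = 1000)
  expect_identical(downsample_cohort(ch, 1), ch)
  half <- downsample_cohort(ch, 0.5, seed = 6)
  for (p in c("2019", "2020", "2021")) {
    n0 <- nrow(cohort_cases(ch, split = "test", period = p))
    n1 <- nrow(cohort_cases(half, split = "test", period = p))
    expect_equal(n1, round(0.5 * n0))
  }
  # retained cases are bit-identical rows of the original
  expect_true(all(half$cases$case_id %in% ch$cases$case_id))
  merged <- merge(half$cases, ch$cases, by = "case_id")
  expect_equal(merged$raw_score.x, merged$raw_score.y)
  expect_error(downsample_cohort(ch, 1.5), class = "shiftmon_input_error")
})

test_that("repeated downsampling preserves incidence on average", {
  ch <- small_cohort(n = 1000, periods = "y", seed = 21)
  orig <- mean(cohort_cases(ch)$label)
  incs <- vapply(1:200, function(s) {
    mean(cohort_cases(downsample_cohort(ch, 0.5, seed = s))$label)
  }, numeric(1))
  n_half <- round(0.5 * nrow(cohort_cases(ch)))
  expect_lt(abs(mean(incs) - orig), 3 * sqrt(orig * (1 - orig) / n_half) / sqrt(200))
})

test_that("incidence thinning retains the pair-count-optimal number of positives", {
  # exhaustive scan oracle: 250 positives, 750 negatives, target 2% -> keep 15
  ks <- 0:250
  gaps <- abs(ks / (ks + 750) - 0.02)
  expect_equal(ks[which.min(gaps)], 15)
  cases <- tibble::tibble(
    case_id = sprintf("c%04d", 1:1000),
    period = "y",
    label = rep(c(1L, 0L), c(250, 750)),
    raw_score = plogis(rnorm(1000)),
    true_prob = plogis(rnorm(1000)),
    onset_time = NA_real_, los = NA_real_,
    split = rep(c("calibration", "test"), length.out = 1000)
  )
  ch <- shiftmon:::new_scored_cohort(cases)
  thin <- thin_incidence(ch, 0.02, seed = 1)
  for (s in c("calibration", "test")) {
    df <- cohort_cases(thin, split = s)
    orig <- cohort_cases(ch, split = s)
    n_neg <- sum(orig$label == 0)
    ks <- 0:sum(orig$label == 1)
    k_best <- ks[which.min(abs(ks / (ks + n_neg) - 0.02))]
    expect_equal(sum(df$label == 1), k_best)
    expect_equal(sum(df$label == 0), n_neg)  # negatives untouched
  }
  expect_error(thin_incidence(ch, 0.30), class = "shiftmon_target_error")
})

test_that("scored-cases CSV round-trips", {
  ch <- generate_cohort(cohort_config(c("a", "b"), 100, 0.2,
                                      simulate_onset = TRUE, seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scored_cases(ch, path)
  back <- read_scored_cases(path)
  expect_equal(as.data.frame(back$cases), as.data.frame(ch$cases))
  # malformed rows are reported
  bad <- ch$cases
  bad$raw_score[3] <- 1.5
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2, na = "")
  expect_error(read_scored_cases(path2), "3", class = "shiftmon_parse_error")
})
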
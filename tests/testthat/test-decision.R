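test_that("threshold selection minimizes |FNR - FPR| with smallest-threshold ties", {
  # separable case: any threshold in (0.2, 0.8] equalizes both rates at 0;
  # the smallest candidate in that range is 0.8
  expect_equal(select_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 0.8)
  # frozen from the brute-force scan: 0.7 attains |1/2 - 1/3| = 1/6
  expect_equal(select_threshold(c(0.1, 0.2, 0.6, 0.7, 0.9), c(0, 0, 1, 0, 1)),
               0.7)
  expect_error(select_threshold(c(0.2, 0.8), c(1, 1)),
               class = "shiftmon_degenerate_error")
})

test_that("selected threshold beats every candidate in an exhaustive scan", {
  withr::local_seed(17)
  for (i in 1:50) {
    inst <- random_instance(sample(10:200, 1),
                            tie_grid = if (i %% 3 == 0) seq(0, 1, 0.05) else NULL)
    probs <- plogis(inst$scores * 4 - 2)
    t_sel <- select_threshold(probs, inst$labels)
    expect_identical(t_sel, brute_force_threshold(probs, inst$labels))
    obj <- function(t) {
      cs <- confusion_summary(probs, inst$labels, t)
      abs(cs$fnr - cs$fpr)
    }
    for (t in unique(c(0, probs, 1))) {
      expect_lte(obj(t_sel), obj(t) + 1e-12)
    }
  }
})

test_that("alert classification covers the five categories", {
  expect_equal(classify_alert(1, TRUE, onset_time = 5, alert_time = 2), "TP")
  expect_equal(classify_alert(1, TRUE, onset_time = 5, alert_time = 6),
               "TP_AFTER_ONSET")
  expect_equal(classify_alert(1, TRUE, onset_time = 5, alert_time = 5),
               "TP_AFTER_ONSET")  # ties are not strictly before onset
  expect_equal(classify_alert(0, TRUE), "FP")
  expect_equal(classify_alert(0, FALSE), "TN")
  expect_equal(classify_alert(1, FALSE), "FN")
  expect_equal(classify_alert(1, TRUE), "TP")  # onset unknown
  expect_error(classify_alert(0, FALSE, onset_time = 2),
               class = "shiftmon_input_error")
  expect_error(classify_alert(1, TRUE, onset_time = 2, alert_time = NA),
               class = "shiftmon_input_error")
})

test_that("confusion summaries match hand enumeration and edge thresholds", {
  cs <- confusion_summary(c(0.9, 0.4, 0.5, 0.2, 0.4), c(1, 1, 0, 0, 0), 0.5)
  expect_equal(cs[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 1L, fp = 1L, fn = 1L, tn = 2L),
               ignore_attr = TRUE)
  expect_equal(cs$alert_rate, 0.4)
  expect_equal(cs$fpr, 1 / 3)
  expect_equal(cs$fnr, 0.5)
  all_in <- confusion_summary(runif(50), rbinom(50, 1, 0.3), 0)
  expect_equal(c(all_in$alert_rate, all_in$fnr), c(1, 0))
  none <- confusion_summary(runif(50, 0.1, 0.9), rbinom(50, 1, 0.3), 1)
  expect_equal(c(none$alert_rate, none$fpr), c(0, 0))
})

test_that("net benefit follows its formula and closed forms", {
  expect_equal(net_benefit(10, 20, 100, 0.2), 0.05)
  expect_equal(net_benefit(7, 99, 200, 0), 7 / 200)
  # treat-all at p_t = prevalence is exactly zero
  pi <- 0.3
  expect_equal(net_benefit(tp = 30, fp = 70, n = 100, p_t = pi),
               pi - (1 - pi) * pi / (1 - pi))
  expect_equal(net_benefit(30, 70, 100, 0.3), 0)
  expect_error(net_benefit(1, 1, 10, 1), class = "shiftmon_input_error")
})

test_that("decision curves honor their invariants", {
  withr::local_seed(19)
  labels <- rbinom(2000, 1, 0.2)
  probs <- plogis(qlogis(0.2) + 2 * labels + rnorm(2000))
  dc <- decision_curve(probs, labels)
  prev <- mean(labels)
  expect_equal(dc$nb_none, rep(0, nrow(dc)))
  expect_equal(dc$nb_model[dc$threshold == 0], prev)
  expect_equal(dc$nb_all[dc$threshold == 0], prev)
  # treat-all crosses zero exactly at the prevalence
  expect_equal(prev - (1 - prev) * prev / (1 - prev), 0)
  expect_true(all(dc$nb_all[dc$threshold < prev] > 0))
  expect_true(all(dc$nb_all[dc$threshold > prev] < 0))
  expect_true(all(dc$nb_model <= prev + 1e-12))
  # perfect classifier: nb_model equals prevalence below the least positive score
  perfect <- decision_curve(ifelse(labels == 1, 0.9, 0.1), labels,
                            thresholds = seq(0, 0.8, 0.1))
  expect_equal(perfect$nb_model[perfect$threshold <= 0.8 &
                                  perfect$threshold > 0.1],
               rep(prev, 7))
  # an uninformative calibrated model tracks the treat-all/treat-none envelope:
  # it alerts everyone below its constant score and no one above it
  unif <- decision_curve(rep(prev, 2000), labels,
                         thresholds = seq(0, 0.9, 0.1))
  expect_equal(unif$nb_model, ifelse(unif$threshold <= prev, unif$nb_all, 0))
})

test_that("incidence standardization augments to the max-incidence target", {
  # exhaustive-scan oracle: 20 positives in 1000, target 3% -> add 10
  ks <- 0:100
  expect_equal(ks[which.min(abs((20 + ks) / (1000 + ks) - 0.03))], 10)
  expect_equal(shiftmon:::augment_k(20, 1000, 0.03), 10)
  cfg <- cohort_config(c("lo", "hi"), 2000, c(0.05, 0.15), seed = 23)
  ch <- generate_cohort(cfg)
  std <- standardize_incidence(ch, seed = 3)
  test0 <- cohort_cases(ch, split = "test")
  test1 <- cohort_cases(std, split = "test")
  target <- max(vapply(split(test0$label, test0$period), mean, numeric(1)))
  inc1 <- vapply(split(test1$label, test1$period), mean, numeric(1))
  expect_true(all(abs(inc1 - target) < 0.002))
  # original cases survive untouched; additions are duplicates of positives
  expect_true(all(test0$case_id %in% test1$case_id))
  added <- test1[grepl("#dup", test1$case_id), ]
  expect_true(all(added$label == 1L))
  expect_true(all(sub("#dup.*", "", added$case_id) %in% test0$case_id))
  # exactly equal empirical incidences -> nothing added
  flat <- shiftmon:::new_scored_cohort(tibble::tibble(
    case_id = sprintf("c%03d", 1:200),
    period = rep(c("a", "b"), each = 100),
    label = rep(rep(c(1L, 0L), c(10, 90)), 2),
    raw_score = plogis(rnorm(200)),
    true_prob = plogis(rnorm(200)),
    onset_time = NA_real_, los = NA_real_,
    split = "test"
  ))
  even <- standardize_incidence(flat, seed = 4)
  expect_equal(nrow(cohort_cases(even)), 200L)
})

test_that("bootstrap curve comparison is null on identical data and detects drift", {
  ch <- generate_cohort(cohort_config("y", 3000, 0.15, seed = 31))
  cases <- cohort_cases(ch)
  same <- compare_decision_curves(
    list(probs = cases$raw_score, labels = cases$label),
    list(probs = cases$raw_score, labels = cases$label),
    n_boot = 500, seed = 1)
  expect_true(all(same$p_value > 0.5))
  # a much weaker model (latent separation 0.5 vs 2) loses net benefit
  weak <- cohort_cases(generate_cohort(
    cohort_config("y", 5000, 0.15, mu_pos = 0.25, mu_neg = -0.25, seed = 32)))
  strong <- cohort_cases(generate_cohort(
    cohort_config("y", 5000, 0.15, seed = 33)))
  cmp <- compare_decision_curves(
    list(probs = strong$raw_score, labels = strong$label),
    list(probs = weak$raw_score, labels = weak$label),
    n_boot = 1000, seed = 2)
  mid <- cmp$threshold %in% c(0.05, 0.10, 0.15, 0.20)
  expect_true(all(cmp$p_value[mid] < 0.05))
  expect_true(all(cmp$delta_nb[mid] > 0))
  expect_error(compare_decision_curves(
    list(probs = cases$raw_score, labels = cases$label),
    list(probs = cases$raw_score, labels = cases$label), n_boot = 50),
    class = "shiftmon_input_error")
})

test_that("the bootstrap comparison holds its size under the null", {
  # 1000 independent null pairs; per-threshold rejection at alpha = .05
  # must stay near nominal
  withr::local_seed(37)
  reject <- matrix(NA, 1000, 6)
  for (i in 1:1000) {
    n <- 1000
    labels_a <- rbinom(n, 1, 0.15)
    labels_b <- rbinom(n, 1, 0.15)
    pa <- plogis(qlogis(0.15) + 2 * labels_a - 1 + rnorm(n))
    pb <- plogis(qlogis(0.15) + 2 * labels_b - 1 + rnorm(n))
    cmp <- compare_decision_curves(list(probs = pa, labels = labels_a),
                                   list(probs = pb, labels = labels_b),
                                   n_boot = 400, seed = i)
    reject[i, ] <- cmp$p_value < 0.05
  }
  rates <- colMeans(reject)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})
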
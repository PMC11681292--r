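# Independent brute-force oracles kept deliberately naive: each re-derives its
# quantity from first principles and never shares code with the implementation.

# AUROC by exhaustive positive-negative pair counting, ties half-credited
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# |FNR - FPR| minimizing threshold by direct scan (smallest-threshold ties)
brute_force_threshold <- function(probs, labels) {
  cand <- sort(unique(c(0, probs, 1)))
  best_t <- NA_real_
  best_obj <- Inf
  for (t in cand) {
    alert <- probs >= t
    fpr <- mean(alert[labels == 0])
    fnr <- mean(!alert[labels == 1])
    obj <- abs(fnr - fpr)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_t <- t
    }
  }
  best_t
}

# random scored instance with both classes and optional tie-heavy scores
random_instance <- function(n, tie_grid = NULL) {
  repeat {
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (any(labels == 1) && any(labels == 0)) break
  }
  scores <- if (is.null(tie_grid)) runif(n) else sample(tie_grid, n, replace = TRUE)
  list(scores = scores, labels = labels)
}

# small drift-free cohort shared across tests
small_cohort <- function(n = 2000, periods = c("2019", "2020", "2021"),
                         incidence = 0.15, seed = 11, ...) {
  generate_cohort(cohort_config(periods, n, incidence, seed = seed, ...))
}
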
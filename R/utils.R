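#' @importFrom stats plogis qlogis pnorm rnorm rbinom runif rmultinom median qnorm
#' @importFrom utils head
#' @importFrom rlang .data
NULL

# run code with a temporary RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_shiftmon <- function(msg, class) {
  rlang::abort(msg, class = c(class, "shiftmon_error"))
}

check_prob_vector <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_shiftmon(sprintf("`%s` must be numeric without missing values.", name),
                  "shiftmon_input_error")
  }
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad) {
    stop_shiftmon(sprintf("`%s` must lie %s 0 and 1.", name,
                          if (open) "strictly between" else "between"),
                  "shiftmon_input_error")
  }
  invisible(x)
}

check_binary_labels <- function(labels, scores = NULL, both_classes = TRUE) {
  if (!all(labels %in% c(0L, 1L))) {
    stop_shiftmon("`labels` must be 0/1.", "shiftmon_input_error")
  }
  if (!is.null(scores) && length(scores) != length(labels)) {
    stop_shiftmon("`scores` and `labels` must have equal length.",
                  "shiftmon_input_error")
  }
  if (both_classes && (sum(labels == 1) == 0 || sum(labels == 0) == 0)) {
    stop_shiftmon("input is degenerate: both classes must be present.",
                  "shiftmon_degenerate_error")
  }
  invisible(as.integer(labels))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}
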
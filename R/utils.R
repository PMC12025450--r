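#' Derive a child random seed
#'
#' Deterministically maps a parent seed and an index to a new seed in
#' `[1, 2^31 - 1]`. The simulation layers use a hierarchy of derived seeds
#' (scenario -> repeat -> bootstrap replicate) so that any single replicate is
#' reproducible in isolation and results do not depend on execution order.
#'
#' @param seed integer parent seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed usable with [set.seed()].
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- as.double(seed) %% m
  s <- (s * 48271 + (as.double(index) %% m) * 16807 + 11) %% m
  as.integer(s + 1)
}

# error helpers with condition classes so the resampling engine can
# distinguish expected statistical failures from programming errors
pi_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "predincr_error")))
}

is_binary01 <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Summarize an empirical distribution of estimates
#'
#' Convenience summary used when inspecting empirical distributions of
#' prediction-increment estimates: location, spread, skewness and the share
#' of mass on each side of zero.
#'
#' @param x numeric vector of estimates.
#' @return a one-row `data.frame` with `n`, `mean`, `median`, `sd`,
#'   `skewness`, `prop_positive` and `shapiro_p` (Shapiro-Wilk normality
#'   p-value, `NA` outside the test's 3..5000 sample-size range).
#' @examples
#' distribution_summary(rexp(100))
#' @export
distribution_summary <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  shapiro_p <- if (n >= 3 && n <= 5000 && stats::sd(x) > 0) {
    stats::shapiro.test(x)$p.value
  } else {
    NA_real_
  }
  data.frame(
    n = n,
    mean = mean(x),
    median = median(x),
    sd = stats::sd(x),
    skewness = sample_skewness(x),
    prop_positive = mean(x > 0),
    shapiro_p = shapiro_p
  )
}
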
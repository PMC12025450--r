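#' Binary-outcome simulation design
#'
#' Describes the class-conditional multivariate-normal generative model for a
#' binary cohort: `Y ~ Bernoulli(event_rate)`, `X | Y = 0 ~ N(mu0, sigma)`,
#' `X | Y = 1 ~ N(mu1, sigma)`. The default means make `x1` a strong standard
#' predictor and `x2`..`x5` candidate markers of null, weak, moderate and
#' strong effect size; with `sigma` the identity the predictors are
#' conditionally independent and the single-marker AUC has the binormal
#' closed form `pnorm(|mu1_k - mu0_k| / sqrt(2))`.
#'
#' @param n number of subjects.
#' @param event_rate marginal event probability, strictly inside (0, 1).
#' @param mu0 covariate mean vector for nonevents.
#' @param mu1 covariate mean vector for events.
#' @param sigma common covariate covariance matrix (symmetric positive
#'   definite).
#' @return an object of class `binary_design`.
#' @seealso [generate_binary_cohort()]
#' @examples
#' binary_design(n = 500, event_rate = 0.1)
#' @export
binary_design <- function(n, event_rate,
                          mu0 = rep(0, 5),
                          mu1 = c(0.7, 0.0, 0.2, 0.5, 0.8),
                          sigma = diag(length(mu0))) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    pi_error("'n' must be a positive integer", "predincr_invalid_design")
  }
  if (!is.numeric(event_rate) || length(event_rate) != 1L ||
      event_rate <= 0 || event_rate >= 1) {
    pi_error("'event_rate' must lie strictly inside (0, 1)",
             "predincr_invalid_design")
  }
  mu0 <- as.numeric(mu0); mu1 <- as.numeric(mu1)
  sigma <- as.matrix(sigma)
  if (length(mu0) != length(mu1) || any(dim(sigma) != length(mu0))) {
    pi_error("dimensions of 'mu0', 'mu1' and 'sigma' must agree",
             "predincr_invalid_design")
  }
  if (!isSymmetric(sigma, tol = 1e-10)) {
    pi_error("'sigma' must be symmetric", "predincr_invalid_design")
  }
  chol_sigma <- tryCatch(chol(sigma), error = function(e) {
    pi_error("'sigma' must be positive definite", "predincr_invalid_design")
  })
  structure(list(n = as.integer(n), event_rate = event_rate,
                 mu0 = mu0, mu1 = mu1, sigma = sigma,
                 chol_sigma = chol_sigma),
            class = "binary_design")
}

#' Right-censored survival simulation design
#'
#' Describes a proportional-hazards Weibull generative model: failure times
#' `U` with baseline Weibull(shape, scale) hazard multiplied by
#' `exp(x' log(hazard_ratios))`, iid standard-normal covariates, and either
#' administrative (type I) censoring at the end of follow-up or uniform
#' random censoring truncated at the end of follow-up. The baseline `scale`
#' is normally left unspecified and calibrated with
#' [calibrate_weibull_scale()] so that the marginal incidence by `followup`
#' equals `incidence_rate`.
#'
#' @param n number of subjects.
#' @param incidence_rate target marginal probability of failure by `followup`,
#'   strictly inside (0, 1).
#' @param hazard_ratios per-covariate hazard ratios (default places a strong
#'   standard marker on `x1` and null/weak/moderate/strong candidates on
#'   `x2`..`x5`).
#' @param shape Weibull shape parameter.
#' @param followup administrative follow-up horizon in years.
#' @param censoring `"type1"` (administrative at `followup`) or `"random"`
#'   (uniform on `(0, random_censoring_max)`, then truncated at `followup`).
#' @param random_censoring_max upper bound of the uniform censoring
#'   distribution; the default `2 * followup` yields light censoring.
#' @param scale Weibull baseline scale; if `NULL` it is calibrated on first
#'   use.
#' @return an object of class `survival_design` with fields including
#'   `log_hazard_ratios`.
#' @seealso [calibrate_weibull_scale()], [generate_survival_cohort()]
#' @examples
#' survival_design(n = 300, incidence_rate = 0.1)
#' @export
survival_design <- function(n, incidence_rate,
                            hazard_ratios = c(2.0, 1.0, 1.2, 1.5, 2.0),
                            shape = 2, followup = 10,
                            censoring = c("type1", "random"),
                            random_censoring_max = 2 * followup,
                            scale = NULL) {
  censoring <- match.arg(censoring)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    pi_error("'n' must be a positive integer", "predincr_invalid_design")
  }
  if (!is.numeric(incidence_rate) || length(incidence_rate) != 1L ||
      incidence_rate <= 0 || incidence_rate >= 1) {
    pi_error("'incidence_rate' must lie strictly inside (0, 1)",
             "predincr_invalid_design")
  }
  if (shape <= 0 || followup <= 0 || (!is.null(scale) && scale <= 0)) {
    pi_error("'shape', 'followup' and 'scale' must be positive",
             "predincr_invalid_design")
  }
  if (any(hazard_ratios <= 0)) {
    pi_error("hazard ratios must be positive", "predincr_invalid_design")
  }
  if (censoring == "random" &&
      (!is.numeric(random_censoring_max) || random_censoring_max <= 0)) {
    pi_error("'random_censoring_max' must be positive",
             "predincr_invalid_design")
  }
  structure(list(n = as.integer(n), incidence_rate = incidence_rate,
                 hazard_ratios = as.numeric(hazard_ratios),
                 log_hazard_ratios = log(as.numeric(hazard_ratios)),
                 shape = shape, followup = followup,
                 censoring = censoring,
                 random_censoring_max = random_censoring_max,
                 scale = scale),
            class = "survival_design")
}

#' @export
print.binary_design <- function(x, ...) {
  cat("Binary cohort design\n")
  cat("  n:", x$n, " event rate:", x$event_rate, "\n")
  cat("  mu1 - mu0:", paste(signif(x$mu1 - x$mu0, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.survival_design <- function(x, ...) {
  cat("Proportional-hazards Weibull cohort design\n")
  cat("  n:", x$n, " incidence by year", x$followup, ":", x$incidence_rate,
      "\n")
  cat("  hazard ratios:", paste(x$hazard_ratios, collapse = ", "), "\n")
  cat("  shape:", x$shape, " scale:",
      if (is.null(x$scale)) "(calibrated on use)" else signif(x$scale, 6),
      "\n")
  cat("  censoring:", x$censoring,
      if (x$censoring == "random") {
        paste0("(uniform on 0..", x$random_censoring_max, ", truncated at ",
               x$followup, ")")
      } else "", "\n")
  invisible(x)
}
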
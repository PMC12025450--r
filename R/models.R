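# Breslow cumulative baseline hazard evaluated on the fitting data.
# Returns a step function table: unique event times and cumulative hazard.
breslow_basehaz <- function(time, status, lp) {
  o <- order(time)
  t_s <- time[o]; s_s <- status[o]; w <- exp(lp[o])
  atrisk <- rev(cumsum(rev(w)))
  ut <- unique(t_s)
  first <- match(ut, t_s)
  d <- as.vector(rowsum(s_s, group = t_s))        # events per unique time
  keep <- d > 0
  list(time = ut[keep], cumhaz = cumsum(d[keep] / atrisk[first][keep]))
}

basehaz_at <- function(bh, tau) {
  idx <- findInterval(tau, bh$time)
  if (idx == 0L) 0 else bh$cumhaz[idx]
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression of the cohort's event indicator on
#' a subset of covariates, via Newton-Raphson with step-halving. By the
#' intercept score equation the mean fitted probability equals the observed
#' event rate (calibration-in-the-large).
#'
#' @param cohort a `cohort` (or any list with `y` and covariate matrix `x`).
#' @param covariates integer indices (or column names) of the covariates to
#'   use, e.g. `1` for the standard model and `c(1, 5)` for an expanded one.
#' @return an object of class `risk_model` with `kind = "logistic"`,
#'   `intercept`, `coefficients`, the covariate indices and convergence
#'   diagnostics.
#' @examples
#' coh <- generate_binary_cohort(binary_design(500, 0.3), seed = 1)
#' fit_logistic(coh, 1)
#' @export
fit_logistic <- function(cohort, covariates) {
  y <- cohort$y
  x <- cohort$x[, covariates, drop = FALSE]
  if (length(y) < 10L) {
    pi_error("need at least 10 subjects", "predincr_invalid_input")
  }
  if (length(unique(y)) < 2L) {
    pi_error("both outcome classes must be present", "predincr_single_class")
  }
  X <- cbind(1, x)
  fit <- .logit_fit_cpp(X, as.numeric(y), 1e-8, 100L)
  eta <- drop(X %*% fit$coef)
  if (fit$separated || min(eta[y == 1]) >= max(eta[y == 0])) {
    pi_error(sprintf("logistic fit separated (max |coef| = %.1f)",
                     max(abs(fit$coef))),
             "predincr_separation", coef = fit$coef)
  }
  if (!fit$converged) {
    pi_error(sprintf("logistic fit did not converge (gradient norm %.3g)",
                     fit$grad_norm),
             "predincr_nonconvergence", grad_norm = fit$grad_norm)
  }
  structure(list(kind = "logistic",
                 covariates = covariates,
                 intercept = fit$coef[1L],
                 coefficients = fit$coef[-1L],
                 iterations = fit$iterations,
                 grad_norm = fit$grad_norm,
                 loglik = fit$loglik),
            class = "risk_model")
}

#' Fit a Cox proportional-hazards risk model
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) by
#' Newton-Raphson with step-halving, and stores the Breslow cumulative
#' baseline hazard so predicted event probabilities at any horizon within the
#' observed follow-up can be formed.
#'
#' @inheritParams fit_logistic
#' @return an object of class `risk_model` with `kind = "cox"`,
#'   `coefficients`, the Breslow baseline hazard table, the largest observed
#'   time and convergence diagnostics.
#' @examples
#' coh <- generate_survival_cohort(survival_design(300, 0.5), seed = 1)
#' fit_cox(coh, c(1, 5))
#' @export
fit_cox <- function(cohort, covariates) {
  y <- cohort$y
  time <- cohort$time
  x <- cohort$x[, covariates, drop = FALSE]
  if (is.null(time) || any(time < 0)) {
    pi_error("cohort must carry nonnegative observed times",
             "predincr_invalid_input")
  }
  if (sum(y) < 2L) {
    pi_error("need at least 2 events", "predincr_single_class")
  }
  o <- order(time)
  ctr <- colMeans(x)
  Xc <- sweep(x, 2L, ctr)[o, , drop = FALSE]
  fit <- .cox_fit_cpp(time[o], as.integer(y[o]), Xc, 1e-8, 100L)
  if (!fit$converged) {
    pi_error(sprintf("Cox fit did not converge (gradient norm %.3g)",
                     fit$grad_norm),
             "predincr_nonconvergence", grad_norm = fit$grad_norm)
  }
  beta <- drop(fit$coef)
  lp <- drop(x %*% beta)      # uncentred linear predictor
  structure(list(kind = "cox",
                 covariates = covariates,
                 coefficients = beta,
                 basehaz = breslow_basehaz(time, y, lp),
                 max_time = max(time),
                 iterations = fit$iterations,
                 grad_norm = fit$grad_norm,
                 loglik = fit$loglik),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(x$kind, "risk model on covariates",
      paste(x$covariates, collapse = ", "), "\n")
  if (x$kind == "logistic") cat("  intercept:", signif(x$intercept, 5), "\n")
  cat("  coefficients:", paste(signif(x$coefficients, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predicted event probabilities
#'
#' For a logistic model, the inverse-logit of the linear predictor; for a Cox
#' model, `1 - S0(horizon)^exp(linear predictor)` with the Breslow baseline
#' survival. Predictions are one-to-one with the risk score.
#'
#' @param model a fitted [fit_logistic()] or [fit_cox()] model.
#' @param cohort the cohort to predict for (same covariate layout).
#' @param horizon prediction horizon in years (required for Cox models; must
#'   not exceed the largest observed time of the fitting data).
#' @return numeric vector of event probabilities in `[0, 1]`.
#' @export
predict_event_probability <- function(model, cohort, horizon = NULL) {
  stopifnot(inherits(model, "risk_model"))
  x <- cohort$x[, model$covariates, drop = FALSE]
  lp <- drop(x %*% model$coefficients)
  if (model$kind == "logistic") {
    return(plogis(model$intercept + lp))
  }
  if (is.null(horizon)) {
    pi_error("Cox predictions require a horizon", "predincr_invalid_input")
  }
  if (horizon > model$max_time + 1e-8) {
    pi_error("horizon lies beyond the last observed time of the fitting data",
             "predincr_invalid_input")
  }
  H0 <- basehaz_at(model$basehaz, horizon)
  1 - exp(-H0 * exp(lp))
}

#' Paired predictions from two nested risk models
#'
#' Aligns per-subject predicted event probabilities from the standard and
#' expanded models; the common input to all prediction-increment measures.
#'
#' @param cohort the cohort both models were fitted on.
#' @param standard_model,expanded_model fitted `risk_model`s; the standard
#'   model's covariates must be a subset of the expanded model's.
#' @param horizon prediction horizon for Cox models.
#' @return a `risk_pairs` data frame with columns `y`, `p_old`, `p_new`,
#'   `z_old`, `z_new` and (survival) `time`.
#' @export
build_risk_pairs <- function(cohort, standard_model, expanded_model,
                             horizon = NULL) {
  if (!all(standard_model$covariates %in% expanded_model$covariates)) {
    pi_error("standard model must be nested in the expanded model",
             "predincr_invalid_input")
  }
  p_old <- predict_event_probability(standard_model, cohort, horizon)
  p_new <- predict_event_probability(expanded_model, cohort, horizon)
  z_old <- drop(cohort$x[, standard_model$covariates, drop = FALSE] %*%
                  standard_model$coefficients)
  z_new <- drop(cohort$x[, expanded_model$covariates, drop = FALSE] %*%
                  expanded_model$coefficients)
  risk_pairs(y = cohort$y, p_old = p_old, p_new = p_new,
             time = cohort$time, z_old = z_old, z_new = z_new)
}

#' Construct paired-prediction data
#'
#' @param y 0/1 event indicators.
#' @param p_old,p_new predicted event probabilities under the standard and
#'   expanded models, in `[0, 1]`.
#' @param time optional observed times (required by survival measures).
#' @param z_old,z_new optional linear predictors.
#' @return a data frame of class `risk_pairs`.
#' @export
risk_pairs <- function(y, p_old, p_new, time = NULL,
                       z_old = NULL, z_new = NULL) {
  if (!is_binary01(y)) {
    pi_error("'y' must be a 0/1 vector without missing values",
             "predincr_invalid_input")
  }
  n <- length(y)
  if (length(p_old) != n || length(p_new) != n ||
      (!is.null(time) && length(time) != n)) {
    pi_error("prediction vectors must align with 'y'",
             "predincr_invalid_input")
  }
  if (anyNA(p_old) || anyNA(p_new) ||
      any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1)) {
    pi_error("predictions must lie in [0, 1]", "predincr_invalid_input")
  }
  out <- data.frame(y = as.integer(y), p_old = p_old, p_new = p_new)
  if (!is.null(time)) out$time <- time
  if (!is.null(z_old)) out$z_old <- z_old
  if (!is.null(z_new)) out$z_new <- z_new
  class(out) <- c("risk_pairs", "data.frame")
  out
}

#' Read paired predictions from a CSV file
#'
#' Expects a header with columns `y`, `p_old`, `p_new` and, for survival
#' data, `time`.
#'
#' @param path path to a CSV file.
#' @return a [risk_pairs()] data frame.
#' @export
read_risk_pairs <- function(path) {
  d <- read.csv(path)
  need <- c("y", "p_old", "p_new")
  if (!all(need %in% names(d))) {
    pi_error("CSV must contain columns y, p_old, p_new",
             "predincr_invalid_input")
  }
  risk_pairs(d$y, d$p_old, d$p_new, time = d[["time"]])
}
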
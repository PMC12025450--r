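# Nested-model fit + predict used by the resampling / coverage loops.
# Returns list(ok = TRUE, p_old, p_new) or list(ok = FALSE, reason = ...).
fit_predict_nested <- function(framework, y, x, time, standard, expanded,
                               horizon = NULL) {
  if (framework == "binary") {
    if (sum(y) == 0L || sum(y) == length(y)) {
      return(list(ok = FALSE, reason = "single_class"))
    }
    yy <- as.numeric(y)
    p <- vector("list", 2L)
    for (m in 1:2) {
      idx <- if (m == 1L) standard else expanded
      X <- cbind(1, x[, idx, drop = FALSE])
      f <- .logit_fit_cpp(X, yy, 1e-8, 100L)
      eta <- drop(X %*% f$coef)
      if (f$separated || min(eta[y == 1]) >= max(eta[y == 0])) {
        return(list(ok = FALSE, reason = "separation"))
      }
      if (!f$converged) return(list(ok = FALSE, reason = "nonconvergence"))
      p[[m]] <- plogis(eta)
    }
    return(list(ok = TRUE, p_old = p[[1L]], p_new = p[[2L]]))
  }
  # survival
  if (sum(y) < 2L) return(list(ok = FALSE, reason = "too_few_events"))
  o <- order(time)
  t_s <- time[o]
  y_s <- as.integer(y[o])
  p <- vector("list", 2L)
  for (m in 1:2) {
    idx <- if (m == 1L) standard else expanded
    xm <- x[, idx, drop = FALSE]
    Xc <- sweep(xm, 2L, colMeans(xm))[o, , drop = FALSE]
    f <- .cox_fit_cpp(t_s, y_s, Xc, 1e-8, 100L)
    if (!f$converged) return(list(ok = FALSE, reason = "nonconvergence"))
    lp <- drop(xm %*% drop(f$coef))
    H0 <- basehaz_at(breslow_basehaz(time, y, lp), horizon)
    p[[m]] <- 1 - exp(-H0 * exp(lp))
  }
  list(ok = TRUE, p_old = p[[1L]], p_new = p[[2L]])
}

#' Bootstrap distributions of prediction-increment measures
#'
#' Measure-agnostic nonparametric bootstrap: each replicate draws `n`
#' subjects with replacement (optionally stratified by event status), refits
#' BOTH nested models on the resample, and recomputes every requested
#' measure. Replicates where a model cannot be fitted (single-class
#' resample, separation, non-convergence) or a measure is undefined
#' (degenerate Kaplan-Meier, no usable pairs) are skipped and logged.
#' Replicate `b` uses the child seed `derive_seed(seed, b)`, so any replicate
#' is reproducible in isolation and the result does not depend on execution
#' order.
#'
#' @param cohort a `cohort`.
#' @param standard,expanded covariate index vectors of the nested models.
#' @param measures canonical measure names (see [compute_measure()]).
#' @param B number of bootstrap replicates (at least 100).
#' @param seed integer seed for the resampling.
#' @param horizon prediction horizon (survival framework).
#' @param cutoffs optional named list of cutoffs per categorical measure;
#'   defaults are resolved from `event_rate`.
#' @param event_rate event rate used for default cutoffs (defaults to the
#'   cohort's sample rate; simulation scenarios pass the design rate).
#' @param stratified resample events and nonevents separately, preserving the
#'   class sizes (guards against all-event / all-nonevent resamples at low
#'   event rates).
#' @param compute_se also compute each measure's asymptotic standard error on
#'   every resample (needed by [bootstrap_t_ci()]; binary framework only).
#'   Either a logical applying to all measures or a character vector naming
#'   the measures that need inner SEs.
#' @param min_valid_fraction minimum fraction of valid replicates below which
#'   the distribution is flagged unusable.
#' @return a named list of `bootstrap_dist` objects (one per measure), each
#'   with `estimates`, optional `inner_ses`, `point_estimate`, `point_se`,
#'   `b_requested`, `b_valid`, `failures` and `usable`.
#' @export
bootstrap_measures <- function(cohort, standard, expanded, measures, B, seed,
                               horizon = NULL, cutoffs = NULL,
                               event_rate = mean(cohort$y),
                               stratified = FALSE, compute_se = FALSE,
                               min_valid_fraction = 0.95) {
  if (B < 100L) {
    pi_error("at least 100 bootstrap replicates are required",
             "predincr_invalid_input")
  }
  y <- cohort$y; x <- cohort$x; time <- cohort$time
  framework <- cohort$framework
  n <- length(y)
  cutlist <- lapply(stats::setNames(measures, measures), function(m) {
    resolve_cutoffs(m, cutoffs[[m]], event_rate)
  })
  need_se <- if (is.character(compute_se)) {
    measures %in% compute_se & measure_has_asymptotic_se(measures)
  } else {
    compute_se & measure_has_asymptotic_se(measures)
  }
  names(need_se) <- measures

  point <- fit_predict_nested(framework, y, x, time, standard, expanded,
                              horizon)
  if (!point$ok) {
    pi_error(paste("model fit failed on the original data:", point$reason),
             "predincr_fit_failure")
  }
  point_est <- point_se <- stats::setNames(numeric(length(measures)),
                                           measures)
  for (m in measures) {
    v <- measure_value(m, y, point$p_old, point$p_new, time,
                       cutlist[[m]], horizon, need_se = TRUE)
    point_est[m] <- v[1L]; point_se[m] <- v[2L]
  }

  est <- matrix(NA_real_, B, length(measures),
                dimnames = list(NULL, measures))
  ses <- matrix(NA_real_, B, length(measures),
                dimnames = list(NULL, measures))
  failures <- character(0)
  idx_ev <- which(y == 1); idx_ne <- which(y == 0)

  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    idx <- if (stratified) {
      c(idx_ev[sample.int(length(idx_ev), replace = TRUE)],
        idx_ne[sample.int(length(idx_ne), replace = TRUE)])
    } else {
      sample.int(n, n, replace = TRUE)
    }
    yb <- y[idx]; xb <- x[idx, , drop = FALSE]
    tb <- if (is.null(time)) NULL else time[idx]
    fit <- fit_predict_nested(framework, yb, xb, tb, standard, expanded,
                              horizon)
    if (!fit$ok) {
      failures <- c(failures, fit$reason)
      next
    }
    for (m in measures) {
      v <- tryCatch(
        measure_value(m, yb, fit$p_old, fit$p_new, tb, cutlist[[m]],
                      horizon, need_se = need_se[m]),
        predincr_error = function(e) {
          failures <<- c(failures, conditionMessage(e))
          c(NA_real_, NA_real_)
        })
      est[b, m] <- v[1L]; ses[b, m] <- v[2L]
    }
  }

  out <- lapply(measures, function(m) {
    ok <- is.finite(est[, m])
    structure(list(measure = m,
                   estimates = est[ok, m],
                   inner_ses = if (need_se[m]) ses[ok, m] else NULL,
                   point_estimate = point_est[[m]],
                   point_se = point_se[[m]],
                   b_requested = B,
                   b_valid = sum(ok),
                   failures = table(failures),
                   usable = sum(ok) / B >= min_valid_fraction),
              class = "bootstrap_dist")
  })
  names(out) <- measures
  out
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat("Bootstrap distribution of ", x$measure, ": ", x$b_valid, "/",
      x$b_requested, " valid replicates\n", sep = "")
  cat("  point estimate:", signif(x$point_estimate, 5), "\n")
  if (x$b_valid > 0) {
    cat("  replicate mean:", signif(mean(x$estimates), 5),
        " sd:", signif(stats::sd(x$estimates), 5), "\n")
  }
  if (!x$usable) cat("  flagged unusable (too many failed replicates)\n")
  invisible(x)
}

check_usable <- function(dist) {
  stopifnot(inherits(dist, "bootstrap_dist"))
  if (!dist$usable || dist$b_valid < 100L) {
    pi_error("bootstrap distribution is unusable (too few valid replicates)",
             "predincr_unusable_bootstrap")
  }
}

# Empirical quantile by linear interpolation between order statistics,
# h = (n + 1) p (quantile type 6); fixed because BC/BCa endpoints depend on
# the rule.
boot_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- pmin(pmax((n + 1) * p, 1), n)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

interval_result <- function(method, lower, upper, alpha, measure = NA) {
  structure(list(method = method, lower = lower, upper = upper,
                 level = 1 - 2 * alpha, alpha = alpha, measure = measure,
                 width = upper - lower),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("%s %.0f%% CI%s: (%.6g, %.6g)  width %.6g\n", x$method,
              100 * x$level,
              if (is.na(x$measure)) "" else paste0(" for ", x$measure),
              x$lower, x$upper, x$width))
  invisible(x)
}

#' Asymptotic (normal-theory) confidence interval
#'
#' `theta_hat +/- z_(1-alpha) * SE` with coverage `1 - 2*alpha`. Only
#' available for measures carrying an asymptotic standard error (the binary
#' framework); survival measures raise an unsupported-method error.
#'
#' @param estimate a [measure_estimate()] with a finite `se`, or a list with
#'   `value` and `se`.
#' @param alpha one-sided tail probability (0.025 for a 95% interval).
#' @return an `interval_result`.
#' @export
asymptotic_ci <- function(estimate, alpha = 0.025) {
  estimate$se <- estimate$se %||% NA_real_
  if (!is.finite(estimate$se)) {
    pi_error("no asymptotic standard error is available for this measure",
             "predincr_unsupported_method")
  }
  z <- qnorm(1 - alpha)
  interval_result("asymptotic", estimate$value - z * estimate$se,
                  estimate$value + z * estimate$se, alpha,
                  measure = estimate$name %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentile bootstrap interval
#'
#' The `alpha` and `1 - alpha` empirical quantiles of the replicate
#' estimates.
#'
#' @param dist a `bootstrap_dist` from [bootstrap_measures()].
#' @param alpha one-sided tail probability.
#' @return an `interval_result`.
#' @export
percentile_ci <- function(dist, alpha = 0.025) {
  check_usable(dist)
  q <- boot_quantile(dist$estimates, c(alpha, 1 - alpha))
  interval_result("percentile", q[1L], q[2L], alpha, dist$measure)
}

#' Bias-corrected (BC) percentile bootstrap interval
#'
#' Median-bias correction: `z0 = qnorm(#\{theta* < theta_hat\} / B)`; the
#' endpoints are the empirical quantiles at the adjusted levels
#' `pnorm(2 z0 + z_alpha)` and `pnorm(2 z0 + z_(1-alpha))`. With `z0 = 0`
#' this is the percentile interval.
#'
#' @inheritParams percentile_ci
#' @return an `interval_result`.
#' @export
bc_ci <- function(dist, alpha = 0.025) {
  check_usable(dist)
  frac <- mean(dist$estimates < dist$point_estimate)
  if (frac <= 0 || frac >= 1) {
    pi_error("all bootstrap replicates lie on one side of the point estimate",
             "predincr_degenerate")
  }
  z0 <- qnorm(frac)
  lev <- pnorm(2 * z0 + qnorm(c(alpha, 1 - alpha)))
  q <- boot_quantile(dist$estimates, lev)
  interval_result("bc", q[1L], q[2L], alpha, dist$measure)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Adds the jackknife acceleration `a` to the BC correction; quantile levels
#' are `pnorm(z0 + (z0 + z_a) / (1 - a (z0 + z_a)))` for each tail. With
#' `z0 = 0` and `a = 0` this is the percentile interval.
#'
#' @inheritParams percentile_ci
#' @param jackknife leave-one-out estimates of the measure on the original
#'   data (see [jackknife_estimates()]).
#' @return an `interval_result`.
#' @export
bca_ci <- function(dist, jackknife, alpha = 0.025) {
  check_usable(dist)
  frac <- mean(dist$estimates < dist$point_estimate)
  if (frac <= 0 || frac >= 1) {
    pi_error("all bootstrap replicates lie on one side of the point estimate",
             "predincr_degenerate")
  }
  z0 <- qnorm(frac)
  u <- mean(jackknife) - jackknife   # influence values
  denom <- sum(u^2)
  if (denom <= 0) {
    pi_error("degenerate jackknife variance", "predincr_degenerate")
  }
  a <- sum(u^3) / (6 * denom^1.5)
  zq <- qnorm(c(alpha, 1 - alpha))
  lev <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  q <- boot_quantile(dist$estimates, lev)
  interval_result("bca", q[1L], q[2L], alpha, dist$measure)
}

#' Bootstrap-t (studentized) interval
#'
#' Uses the pivot `t*_b = (theta*_b - theta_hat) / se*_b` with each
#' replicate's own standard error (the measure's asymptotic SE formula
#' evaluated on the resample), giving endpoints
#' `theta_hat - t*_(1-alpha) se_hat` and `theta_hat - t*_(alpha) se_hat`.
#' Replicates with a zero or missing inner SE are skipped; more than 5%
#' skipped raises an error.
#'
#' @inheritParams percentile_ci
#' @return an `interval_result`.
#' @export
bootstrap_t_ci <- function(dist, alpha = 0.025) {
  check_usable(dist)
  if (is.null(dist$inner_ses)) {
    pi_error(
      "bootstrap-t needs inner SEs: rerun bootstrap_measures(compute_se = TRUE)",
      "predincr_unsupported_method")
  }
  if (!is.finite(dist$point_se) || dist$point_se <= 0) {
    pi_error("the original estimate has no positive standard error",
             "predincr_degenerate")
  }
  ok <- is.finite(dist$inner_ses) & dist$inner_ses > 0
  if (mean(!ok) > 0.05) {
    pi_error("more than 5% of replicates have degenerate inner SEs",
             "predincr_unusable_bootstrap")
  }
  t_piv <- (dist$estimates[ok] - dist$point_estimate) / dist$inner_ses[ok]
  q <- boot_quantile(t_piv, c(alpha, 1 - alpha))
  interval_result("bootstrap_t",
                  dist$point_estimate - q[2L] * dist$point_se,
                  dist$point_estimate - q[1L] * dist$point_se,
                  alpha, dist$measure)
}

#' Hybrid (basic) bootstrap interval
#'
#' Percentile endpoints reflected about the point estimate:
#' `(2 theta_hat - q_(1-alpha), 2 theta_hat - q_alpha)`.
#'
#' @inheritParams percentile_ci
#' @return an `interval_result`.
#' @export
hybrid_ci <- function(dist, alpha = 0.025) {
  check_usable(dist)
  q <- boot_quantile(dist$estimates, c(alpha, 1 - alpha))
  interval_result("hybrid", 2 * dist$point_estimate - q[2L],
                  2 * dist$point_estimate - q[1L], alpha, dist$measure)
}

#' Leave-one-out jackknife estimates of a measure
#'
#' Refits both nested models on each leave-one-out subsample and recomputes
#' the measure; the input to the BCa acceleration.
#'
#' @inheritParams bootstrap_measures
#' @param measure a single canonical measure name.
#' @return numeric vector of `n` leave-one-out estimates.
#' @export
jackknife_estimates <- function(cohort, standard, expanded, measure,
                                horizon = NULL, cutoffs = NULL,
                                event_rate = mean(cohort$y)) {
  y <- cohort$y; x <- cohort$x; time <- cohort$time
  n <- length(y)
  cuts <- resolve_cutoffs(measure, cutoffs, event_rate)
  vapply(seq_len(n), function(i) {
    yi <- y[-i]; xi <- x[-i, , drop = FALSE]
    ti <- if (is.null(time)) NULL else time[-i]
    fit <- fit_predict_nested(cohort$framework, yi, xi, ti, standard,
                              expanded, horizon)
    if (!fit$ok) return(NA_real_)
    tryCatch(
      measure_value(measure, yi, fit$p_old, fit$p_new, ti, cuts, horizon)[1L],
      predincr_error = function(e) NA_real_)
  }, numeric(1))
}
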
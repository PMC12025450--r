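marker_covariate_map <- c(null = 2L, weak = 3L, moderate = 4L, strong = 5L)

#' Simulation scenario configuration
#'
#' One cell of the coverage-study grid: a generative design (binary or
#' survival framework, event/incidence rate, sample size, censoring), the
#' nested-model comparison implied by the added-marker strength, and the
#' Monte-Carlo knobs (number of repeats `K`, bootstrap replicates `B`, tail
#' probability `alpha`, master seed). The standard model always uses `x1`;
#' the added marker maps to `x2` (null), `x3` (weak), `x4` (moderate) or
#' `x5` (strong) — binary effect sizes 0.0 / 0.2 / 0.5 / 0.8 on the event
#' mean, survival hazard ratios 1.0 / 1.2 / 1.5 / 2.0.
#'
#' @param framework `"binary"` or `"survival"`.
#' @param event_rate marginal event rate (binary) or incidence by the end of
#'   follow-up (survival).
#' @param marker strength of the added marker: `"strong"`, `"moderate"`,
#'   `"weak"` or `"null"`.
#' @param n per-repeat cohort size.
#' @param censoring survival censoring mechanism (see [survival_design()]).
#' @param K number of simulation repeats.
#' @param B bootstrap replicates per repeat.
#' @param alpha one-sided tail probability of the intervals.
#' @param master_seed seed from which all repeat and replicate seeds derive.
#' @param stratified stratify bootstrap resampling by event status.
#' @param random_censoring_max upper bound of the uniform censoring
#'   distribution (random censoring only).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(framework = c("binary", "survival"),
                            event_rate = 0.10,
                            marker = c("strong", "moderate", "weak", "null"),
                            n = 2000,
                            censoring = c("type1", "random"),
                            K = 1000, B = 2000, alpha = 0.025,
                            master_seed = 1,
                            stratified = FALSE,
                            random_censoring_max = 20) {
  framework <- match.arg(framework)
  marker <- match.arg(marker)
  censoring <- match.arg(censoring)
  added <- marker_covariate_map[[marker]]
  design <- if (framework == "binary") {
    binary_design(n = n, event_rate = event_rate)
  } else {
    survival_design(n = n, incidence_rate = event_rate,
                    censoring = censoring,
                    random_censoring_max = random_censoring_max)
  }
  structure(list(framework = framework, event_rate = event_rate,
                 marker = marker, n = as.integer(n),
                 censoring = if (framework == "survival") censoring else NA,
                 design = design,
                 standard = 1L, expanded = c(1L, added),
                 horizon = if (framework == "survival") design$followup
                           else NULL,
                 K = as.integer(K), B = as.integer(B), alpha = alpha,
                 master_seed = as.integer(master_seed),
                 stratified = stratified),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$framework, "framework, rate", x$event_rate,
      ",", x$marker, "added marker, n =", x$n, "\n")
  if (x$framework == "survival") cat("  censoring:", x$censoring, "\n")
  cat("  K =", x$K, "repeats, B =", x$B, "bootstrap replicates, alpha =",
      x$alpha, ", master seed", x$master_seed, "\n")
  invisible(x)
}

scenario_design_with_n <- function(scenario, n) {
  d <- scenario$design
  d$n <- as.integer(n)
  d
}

generate_scenario_cohort <- function(scenario, seed, n = scenario$n) {
  d <- scenario_design_with_n(scenario, n)
  if (scenario$framework == "binary") {
    generate_binary_cohort(d, seed)
  } else {
    generate_survival_cohort(d, seed)
  }
}

default_scenario_measures <- function(scenario) {
  if (scenario$framework == "binary") binary_measure_keys
  else survival_measure_keys
}

#' Reference ("true") value of a measure under a scenario
#'
#' The population value used to score coverage: the plug-in estimate on a
#' single mega-cohort drawn from the scenario's generative design with a
#' fixed internal seed (independent of the scenario's master seed, so the
#' truth does not vary across runs). For the binary `delta_auc` the
#' mega-sample value is cross-checked against the binormal closed form
#' `pnorm(|mu1 - mu0|_expanded / sqrt(2)) - pnorm(|mu1 - mu0|_standard /
#' sqrt(2))`; a disagreement beyond 5 Monte-Carlo standard errors raises an
#' error (it would indicate a generator or measure defect).
#'
#' @param scenario a [scenario_config()].
#' @param measure canonical measure name.
#' @param n_mega mega-cohort size (default 1e6 binary, 1e5 survival; the
#'   survival concordance is quadratic in `n`).
#' @param seed fixed internal seed of the mega-cohort.
#' @return a list with `value`, `provenance`, `n_mega` and, for binary
#'   `delta_auc`, `closed_form`.
#' @export
true_value <- function(scenario, measure, n_mega = NULL, seed = 190711L) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(n_mega)) {
    n_mega <- if (scenario$framework == "binary") 1e6 else 1e5
  }
  coh <- generate_scenario_cohort(scenario, seed, n = n_mega)
  fit <- fit_predict_nested(scenario$framework, coh$y, coh$x, coh$time,
                            scenario$standard, scenario$expanded,
                            scenario$horizon)
  if (!fit$ok) {
    pi_error(paste("mega-cohort model fit failed:", fit$reason),
             "predincr_fit_failure")
  }
  cuts <- resolve_cutoffs(measure, NULL, scenario$event_rate)
  need_se <- scenario$framework == "binary" && measure == "delta_auc"
  v <- measure_value(measure, coh$y, fit$p_old, fit$p_new, coh$time,
                     cuts, scenario$horizon, need_se = need_se)
  out <- list(value = v[1L], provenance = "mega-sample plug-in",
              n_mega = n_mega)
  if (need_se) {
    d <- scenario$design$mu1 - scenario$design$mu0
    cf <- pnorm(sqrt(sum(d[scenario$expanded]^2)) / sqrt(2)) -
      pnorm(sqrt(sum(d[scenario$standard]^2)) / sqrt(2))
    if (is.finite(v[2L]) && abs(v[1L] - cf) > 5 * max(v[2L], 1e-12)) {
      pi_error(sprintf(
        "mega-sample delta AUC %.5f disagrees with the closed form %.5f",
        v[1L], cf), "predincr_degenerate")
    }
    out$closed_form <- cf
  }
  out
}

#' Empirical distribution of measure estimates
#'
#' Draws `iterations` independent cohorts of size `n_large` from the
#' scenario's design, refits both nested models on each, and records every
#' measure: the raw material for distribution-shape diagnostics (the
#' estimates under a null added marker are right-skewed with median near
#' zero, while strong-marker distributions are close to symmetric).
#'
#' @param scenario a [scenario_config()].
#' @param measures canonical measure names (default: all for the framework).
#' @param n_large per-iteration cohort size.
#' @param iterations number of iterations.
#' @param seed seed (defaults to the scenario's master seed).
#' @return a data frame of estimates (one row per iteration) with a
#'   `"summary"` attribute of per-measure [distribution_summary()] rows.
#' @export
empirical_distribution <- function(scenario, measures = NULL,
                                   n_large = 1e4, iterations = 300,
                                   seed = scenario$master_seed) {
  measures <- measures %||% default_scenario_measures(scenario)
  est <- matrix(NA_real_, iterations, length(measures),
                dimnames = list(NULL, measures))
  cuts <- lapply(stats::setNames(measures, measures), resolve_cutoffs,
                 cutoffs = NULL, event_rate = scenario$event_rate)
  for (it in seq_len(iterations)) {
    coh <- generate_scenario_cohort(scenario, derive_seed(seed, it),
                                    n = n_large)
    fit <- fit_predict_nested(scenario$framework, coh$y, coh$x, coh$time,
                              scenario$standard, scenario$expanded,
                              scenario$horizon)
    if (!fit$ok) next
    for (m in measures) {
      est[it, m] <- measure_value(m, coh$y, fit$p_old, fit$p_new, coh$time,
                                  cuts[[m]], scenario$horizon)[1L]
    }
  }
  out <- as.data.frame(est)
  summ <- do.call(rbind, lapply(measures, function(m) {
    cbind(measure = m, distribution_summary(est[, m]))
  }))
  attr(out, "summary") <- summ
  out
}

ci_method_names <- c("asymptotic", "percentile", "bc", "bca", "bootstrap_t",
                     "hybrid")

#' Run one coverage-study scenario
#'
#' Draws `K` independent cohorts from the scenario design; on each, fits the
#' nested models, computes the requested measures and confidence intervals,
#' and scores each interval against the reference value from [true_value()].
#' Asymptotic intervals are available in the binary framework only (the
#' survival measures carry no standard-error formulas). Fully deterministic
#' given the scenario's master seed; repeats use derived seeds and are
#' independent work units.
#'
#' @param scenario a [scenario_config()].
#' @param measures canonical measure names (default: all for the framework).
#' @param methods interval methods among `"asymptotic"`, `"percentile"`,
#'   `"bc"`, `"bca"`, `"bootstrap_t"`, `"hybrid"`.
#' @param truth optional named vector of reference values (computed by
#'   [true_value()] when missing).
#' @param n_mega mega-cohort size passed to [true_value()].
#' @param inner_se_measures measures whose asymptotic SE is evaluated on each
#'   bootstrap resample for [bootstrap_t_ci()]; defaults to all requested
#'   measures when `"bootstrap_t"` is among the methods.
#' @param verbose print progress every 50 repeats.
#' @return a data frame with one row per measure x method: the scenario
#'   descriptors, `theta_true`, `coverage` (percent), `mc_se` (percentage
#'   points), `mean_width`, `bias` (mean point estimate minus truth),
#'   `n_intervals` and `K`. The matrix of per-repeat point estimates is
#'   attached as attribute `"point_estimates"`.
#' @export
run_scenario <- function(scenario, measures = NULL,
                         methods = c("asymptotic", "percentile", "bc",
                                     "bootstrap_t", "hybrid"),
                         truth = NULL, n_mega = NULL,
                         inner_se_measures = NULL, verbose = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"))
  measures <- measures %||% default_scenario_measures(scenario)
  methods <- match.arg(methods, ci_method_names, several.ok = TRUE)
  if (scenario$framework == "survival" && "asymptotic" %in% methods) {
    pi_error(paste("asymptotic intervals are not available in the survival",
                   "framework (no standard-error formulas)"),
             "predincr_unsupported_method")
  }
  boot_methods <- setdiff(methods, "asymptotic")
  need_boot <- length(boot_methods) > 0L
  compute_se <- if ("bootstrap_t" %in% methods) {
    if (is.null(inner_se_measures)) TRUE else inner_se_measures
  } else FALSE
  need_jack <- "bca" %in% methods
  alpha <- scenario$alpha

  if (is.null(truth)) {
    truth <- vapply(measures, function(m) {
      true_value(scenario, m, n_mega = n_mega)$value
    }, numeric(1))
  }
  if (is.null(names(truth))) names(truth) <- measures
  stopifnot(all(measures %in% names(truth)))

  cuts <- lapply(stats::setNames(measures, measures), resolve_cutoffs,
                 cutoffs = NULL, event_rate = scenario$event_rate)
  K <- scenario$K
  est <- matrix(NA_real_, K, length(measures),
                dimnames = list(NULL, measures))
  covered <- width <- array(
    NA_real_, c(K, length(measures), length(methods)),
    dimnames = list(NULL, measures, methods))
  failed_repeats <- 0L

  for (k in seq_len(K)) {
    seed_k <- derive_seed(scenario$master_seed, k)
    coh <- generate_scenario_cohort(scenario, seed_k)
    fit <- fit_predict_nested(scenario$framework, coh$y, coh$x, coh$time,
                              scenario$standard, scenario$expanded,
                              scenario$horizon)
    if (!fit$ok) { failed_repeats <- failed_repeats + 1L; next }

    point <- lapply(stats::setNames(measures, measures), function(m) {
      tryCatch(
        measure_value(m, coh$y, fit$p_old, fit$p_new, coh$time, cuts[[m]],
                      scenario$horizon,
                      need_se = measure_has_asymptotic_se(m)),
        predincr_error = function(e) c(NA_real_, NA_real_))
    })
    for (m in measures) est[k, m] <- point[[m]][1L]

    dists <- NULL
    if (need_boot) {
      dists <- tryCatch(
        bootstrap_measures(coh, scenario$standard, scenario$expanded,
                           measures, B = scenario$B,
                           seed = derive_seed(seed_k, 1000003L),
                           horizon = scenario$horizon,
                           event_rate = scenario$event_rate,
                           stratified = scenario$stratified,
                           compute_se = compute_se),
        predincr_error = function(e) NULL)
      if (is.null(dists)) { failed_repeats <- failed_repeats + 1L; next }
    }

    for (m in measures) {
      jack <- if (need_jack) {
        jackknife_estimates(coh, scenario$standard, scenario$expanded, m,
                            horizon = scenario$horizon,
                            event_rate = scenario$event_rate)
      }
      for (meth in methods) {
        ci <- tryCatch(
          switch(meth,
            asymptotic = asymptotic_ci(
              list(value = point[[m]][1L], se = point[[m]][2L], name = m),
              alpha),
            percentile = percentile_ci(dists[[m]], alpha),
            bc = bc_ci(dists[[m]], alpha),
            bca = bca_ci(dists[[m]], jack[is.finite(jack)], alpha),
            bootstrap_t = bootstrap_t_ci(dists[[m]], alpha),
            hybrid = hybrid_ci(dists[[m]], alpha)),
          predincr_error = function(e) NULL)
        if (is.null(ci)) next
        covered[k, m, meth] <- as.numeric(
          truth[[m]] >= ci$lower && truth[[m]] <= ci$upper)
        width[k, m, meth] <- ci$width
      }
    }
    if (verbose && k %% 50L == 0L) {
      message("repeat ", k, "/", K)
    }
  }

  if (failed_repeats > 0.01 * K) {
    pi_error(sprintf("%d of %d repeats failed entirely", failed_repeats, K),
             "predincr_scenario_failure")
  }

  rows <- expand.grid(measure = measures, method = methods,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$measure[i]; meth <- rows$method[i]
    cov_k <- covered[, m, meth]
    n_int <- sum(is.finite(cov_k))
    cov <- if (n_int > 0) mean(cov_k, na.rm = TRUE) else NA_real_
    data.frame(framework = scenario$framework,
               event_rate = scenario$event_rate,
               marker = scenario$marker, n = scenario$n,
               censoring = scenario$censoring,
               K = K, B = scenario$B,
               measure = m, method = meth,
               theta_true = truth[[m]],
               coverage = 100 * cov,
               mc_se = 100 * sqrt(cov * (1 - cov) / max(n_int, 1L)),
               mean_width = mean(width[, m, meth], na.rm = TRUE),
               bias = mean(est[, m], na.rm = TRUE) - truth[[m]],
               n_intervals = n_int,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "point_estimates") <- est
  out
}

#' Classify and tabulate coverage results over a scenario grid
#'
#' Applies the acceptable-coverage band (closed interval, by default 94--96
#' percent) to each scenario x measure x method coverage estimate and
#' tabulates the share of low / acceptable / high cells by interval method,
#' by measure, and jointly. Also returns a wide method x measure coverage
#' table per scenario cell.
#'
#' @param results one or more [run_scenario()] outputs, row-bound.
#' @param band closed acceptable-coverage interval in percent.
#' @return a list with `classified` (the input plus a `class` column),
#'   `by_method`, `by_measure`, `by_method_measure` proportion tables, and
#'   `wide` (coverage pivoted method x measure within each scenario cell).
#' @export
summarize_grid <- function(results, band = c(94, 96)) {
  stopifnot(all(c("coverage", "method", "measure") %in% names(results)))
  cls <- ifelse(results$coverage < band[1L], "low",
                ifelse(results$coverage > band[2L], "high", "acceptable"))
  results$class <- factor(cls, levels = c("low", "acceptable", "high"))
  prop_tab <- function(by) {
    t <- table(results[[by]], results$class)
    as.data.frame.matrix(prop.table(t, margin = 1))
  }
  wide <- stats::reshape(
    results[, c("framework", "event_rate", "marker", "n", "method",
                "measure", "coverage")],
    idvar = c("framework", "event_rate", "marker", "n", "method"),
    timevar = "measure", direction = "wide")
  names(wide) <- sub("^coverage\\.", "", names(wide))
  list(classified = results,
       by_method = prop_tab("method"),
       by_measure = prop_tab("measure"),
       by_method_measure = tapply(results$class == "acceptable",
                                  list(results$method, results$measure),
                                  mean),
       wide = wide,
       band = band)
}
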
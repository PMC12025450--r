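# Measure registry ----------------------------------------------------------
#
# Canonical measure keys used by the resampling engine and the coverage
# driver:
#   binary:   "delta_auc", "nri_cat2", "nri_cat3", "nri_gt0", "idi"
#   survival: "delta_c", "nri_t_cat2", "nri_t_cat3", "nri_t_cont", "idi_t"
# The *_cat2 / *_cat3 variants are the categorical (e)NRI with the default
# two- and three-category cutoffs for the scenario's event rate.

binary_measure_keys <- c("delta_auc", "nri_cat2", "nri_cat3", "nri_gt0",
                         "idi")
survival_measure_keys <- c("delta_c", "nri_t_cat2", "nri_t_cat3",
                           "nri_t_cont", "idi_t")

measure_has_asymptotic_se <- function(measure) {
  measure %in% binary_measure_keys
}

resolve_cutoffs <- function(measure, cutoffs, event_rate) {
  if (!is.null(cutoffs)) return(cutoffs)
  if (grepl("cat2$", measure)) return(default_cutoffs(event_rate, 2))
  if (grepl("cat3$", measure)) return(default_cutoffs(event_rate, 3))
  NULL
}

# Fast internal evaluator used inside the bootstrap and coverage loops:
# returns c(value, se) without building S3 objects. `se` is NA unless
# requested and defined for the measure.
measure_value <- function(measure, y, p_old, p_new, time = NULL,
                          cutoffs = NULL, horizon = NULL, need_se = FALSE) {
  switch(measure,
    delta_auc = {
      if (need_se) {
        r <- delta_auc_core(y, p_old, p_new, TRUE)
        c(r$value, r$se)
      } else {
        yi <- as.integer(y)
        c(.cstat_cpp(p_new, yi) - .cstat_cpp(p_old, yi), NA_real_)
      }
    },
    nri_cat2 = ,
    nri_cat3 = {
      co <- risk_category(p_old, cutoffs)
      cn <- risk_category(p_new, cutoffs)
      nri_counts(y, cn > co, cn < co, need_se)
    },
    nri_gt0 = nri_counts(y, p_new > p_old, p_new < p_old, need_se),
    idi = {
      ev <- y == 1
      d <- p_new - p_old
      n1 <- sum(ev); n0 <- length(y) - n1
      v <- mean(d[ev]) - mean(d[!ev])
      s <- if (need_se) sqrt(var(d[ev]) / n1 + var(d[!ev]) / n0) else NA_real_
      c(v, s)
    },
    delta_c = {
      res <- .concordance_cpp(time, as.integer(y), cbind(p_new, p_old), 0.5)
      if (res$usable == 0) pi_error("no usable pairs", "predincr_degenerate")
      c(res$c[1L] - res$c[2L], NA_real_)
    },
    nri_t_cat2 = ,
    nri_t_cat3 = {
      co <- risk_category(p_old, cutoffs)
      cn <- risk_category(p_new, cutoffs)
      r <- nri_t_core(y, time, cn > co, cn < co, horizon, 0.5, "km")
      c(r$value, NA_real_)
    },
    nri_t_cont = {
      r <- nri_t_core(y, time, p_new > p_old, p_new < p_old, horizon, 0.5,
                      "km")
      c(r$value, NA_real_)
    },
    idi_t = {
      s_t <- km_survival(kaplan_meier(time, y), horizon)
      if (s_t <= 0 || s_t >= 1) {
        pi_error("degenerate Kaplan-Meier survival at the horizon",
                 "predincr_degenerate")
      }
      c((var(1 - p_new) - var(1 - p_old)) / (s_t * (1 - s_t)), NA_real_)
    },
    pi_error(paste("unknown measure:", measure), "predincr_invalid_input")
  )
}

nri_counts <- function(y, up, down, need_se) {
  ev <- y == 1
  n1 <- sum(ev); n0 <- length(y) - n1
  up1 <- sum(up & ev) / n1; down1 <- sum(down & ev) / n1
  up0 <- sum(up & !ev) / n0; down0 <- sum(down & !ev) / n0
  v <- (up1 - down1) + (down0 - up0)
  s <- NA_real_
  if (need_se) {
    s <- sqrt((up1 + down1) / n1 - (up1 - down1)^2 / n1 +
                (down0 + up0) / n0 - (down0 - up0)^2 / n0)
  }
  c(v, s)
}

#' Compute a prediction-increment measure by name
#'
#' Front end over [delta_auc()], [nri_categorical()], [nri_continuous()],
#' [idi()], [delta_c()], [nri_t()] and [idi_t()] keyed by the canonical
#' measure names used by the resampling engine and coverage driver:
#' `"delta_auc"`, `"nri_cat2"`, `"nri_cat3"`, `"nri_gt0"`, `"idi"`
#' (binary framework) and `"delta_c"`, `"nri_t_cat2"`, `"nri_t_cat3"`,
#' `"nri_t_cont"`, `"idi_t"` (survival framework).
#'
#' @param pairs a [risk_pairs()] data frame.
#' @param measure canonical measure name.
#' @param cutoffs interior category cutoffs for the categorical variants; if
#'   `NULL`, [default_cutoffs()] of `event_rate` is used.
#' @param horizon evaluation time for survival measures.
#' @param event_rate event rate used to resolve default cutoffs (defaults to
#'   the sample event rate of `pairs`).
#' @return a [measure_estimate()].
#' @export
compute_measure <- function(pairs, measure, cutoffs = NULL, horizon = NULL,
                            event_rate = mean(pairs$y)) {
  cutoffs <- resolve_cutoffs(measure, cutoffs, event_rate)
  switch(measure,
    delta_auc = delta_auc(pairs),
    nri_cat2 = ,
    nri_cat3 = nri_categorical(pairs, cutoffs),
    nri_gt0 = nri_continuous(pairs),
    idi = idi(pairs),
    delta_c = delta_c(pairs),
    nri_t_cat2 = ,
    nri_t_cat3 = nri_t(pairs, horizon, cutoffs = cutoffs),
    nri_t_cont = nri_t(pairs, horizon),
    idi_t = idi_t(pairs, horizon),
    pi_error(paste("unknown measure:", measure), "predincr_invalid_input")
  )
}
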
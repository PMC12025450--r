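#' Kaplan-Meier product-limit curve
#'
#' @param time nonnegative observed times.
#' @param event 0/1 event indicators.
#' @return an object of class `km_curve` with the distinct times, numbers at
#'   risk, event counts and the right-continuous step survival function.
#' @seealso [km_survival()] to evaluate the curve.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) {
    pi_error("empty input", "predincr_invalid_input")
  }
  if (any(time < 0) || !is_binary01(event) || length(event) != length(time)) {
    pi_error("'time' must be nonnegative and 'event' a matching 0/1 vector",
             "predincr_invalid_input")
  }
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  ut <- unique(t_s)
  first <- match(ut, t_s)
  n <- length(t_s)
  n_risk <- n - first + 1L
  d <- as.vector(rowsum(e_s, group = t_s))
  surv <- cumprod(1 - d / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = d, surv = surv,
                 n = n), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Returns the step value `S(t)` at the largest tabulated time `<= t`
#' (right-continuous); 1 before the first observed time.
#'
#' @param km a [kaplan_meier()] curve.
#' @param t times at which to evaluate.
#' @return survival probabilities.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  out <- c(1, km$surv)[idx + 1L]
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event),
      ", final S =", signif(x$surv[length(x$surv)], 4), "\n")
  invisible(x)
}

km_event_prob <- function(time, event, horizon) {
  1 - km_survival(kaplan_meier(time, event), horizon)
}

#' Harrell's overall C for censored data
#'
#' The proportion of usable concordant pairs. A pair is usable when the
#' strictly smaller observed time belongs to an event (events are comparable
#' with later events and with later-censored subjects); pairs with tied
#' observed times are not orderable and are skipped. Within a usable pair the
#' earlier subject should carry the higher predicted risk: concordance scores
#' 1, prediction ties score `tie_credit` (0.5 by default; set 0 for the
#' strict convention).
#'
#' @param risk predicted risks (higher = shorter survival).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param tie_credit credit for prediction ties.
#' @return a [measure_estimate()] named `"overall_c"` with the usable-pair
#'   count in its metadata.
#' @export
overall_c <- function(risk, time, event, tie_credit = 0.5) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  res <- .concordance_cpp(as.numeric(time), as.integer(event),
                          matrix(as.numeric(risk), ncol = 1), tie_credit)
  if (res$usable == 0) {
    pi_error("no usable pairs", "predincr_degenerate")
  }
  measure_estimate("overall_c", res$c[1L],
                   n_events = sum(event == 1), n_nonevents = sum(event == 0),
                   metadata = list(usable_pairs = res$usable,
                                   tie_credit = tie_credit))
}

#' Change in overall C between nested models
#'
#' `C(p_new) - C(p_old)` computed over the same usable-pair set.
#'
#' @param pairs a [risk_pairs()] data frame carrying `time`.
#' @param tie_credit credit for prediction ties (see [overall_c()]).
#' @return a [measure_estimate()] named `"delta_c"` with components `c_new`,
#'   `c_old`.
#' @export
delta_c <- function(pairs, tie_credit = 0.5) {
  if (is.null(pairs$time)) {
    pi_error("'pairs' must carry observed times", "predincr_invalid_input")
  }
  res <- .concordance_cpp(as.numeric(pairs$time), as.integer(pairs$y),
                          cbind(pairs$p_new, pairs$p_old), tie_credit)
  if (res$usable == 0) {
    pi_error("no usable pairs", "predincr_degenerate")
  }
  measure_estimate("delta_c", res$c[1L] - res$c[2L],
                   n_events = sum(pairs$y == 1),
                   n_nonevents = sum(pairs$y == 0),
                   components = list(c_new = res$c[1L], c_old = res$c[2L]),
                   metadata = list(usable_pairs = res$usable))
}

# core survival NRI(t) computation shared by the KM and count estimators
nri_t_core <- function(y, time, up, down, horizon, w, estimator) {
  p_up <- mean(up); p_down <- mean(down)
  if (estimator == "km") {
    p <- km_event_prob(time, y, horizon)
    if (p <= 0 || p >= 1) {
      pi_error("marginal event probability at the horizon is degenerate",
               "predincr_degenerate")
    }
    pr <- function(sel) {
      if (!any(sel)) return(0)
      km_event_prob(time[sel], y[sel], horizon)
    }
    p1_up <- pr(up); p1_down <- pr(down)
    # Bayes decomposition of the class-conditional movement probabilities
    nri_ev <- (p1_up * p_up - p1_down * p_down) / p
    nri_ne <- ((1 - p1_down) * p_down - (1 - p1_up) * p_up) / (1 - p)
  } else {
    ev_t <- y == 1 & time <= horizon   # known events by the horizon
    ne_t <- time > horizon             # known event-free at the horizon
    n1 <- sum(ev_t); n0 <- sum(ne_t)
    if (n1 == 0L || n0 == 0L) {
      pi_error("no known events or no known nonevents at the horizon",
               "predincr_degenerate")
    }
    nri_ev <- (sum(up & ev_t) - sum(down & ev_t)) / n1
    nri_ne <- (sum(down & ne_t) - sum(up & ne_t)) / n0
  }
  value <- if (w == 0.5) nri_ev + nri_ne else w * nri_ev + (1 - w) * nri_ne
  list(value = value, nri_events = nri_ev, nri_nonevents = nri_ne,
       p_up = p_up, p_down = p_down)
}

#' Survival net reclassification improvement NRI(t)
#'
#' Classifies subjects into upward / downward / unchanged movement groups
#' (category movement when `cutoffs` is supplied, strict risk increase or
#' decrease otherwise) and estimates the class-conditional movement
#' probabilities at the horizon. The default `"km"` estimator applies Bayes'
#' theorem with Kaplan-Meier estimates of `P(Y(t)=1 | Z_up)`,
#' `P(Y(t)=1 | Z_down)` and the marginal `p = P(Y(t)=1)` to account for
#' censoring; the `"count"` estimator uses raw counts among subjects whose
#' status at the horizon is known. With `w = 0.5` the reported value is
#' `2 * NRI_0.5(t)`, the scale of the binary NRI; with zero censoring and the
#' count reduction it equals the binary measure exactly. Movement groups with
#' no members contribute zero; subgroup Kaplan-Meier curves with no events by
#' the horizon yield a conditional event probability of zero.
#'
#' @param pairs a [risk_pairs()] data frame carrying `time`.
#' @param horizon evaluation time t.
#' @param cutoffs interior risk-category cutoffs, or `NULL` for the
#'   continuous version.
#' @param w event-component weight; the default 0.5 gives the doubled
#'   (binary-scale) NRI.
#' @param estimator `"km"` (default) or `"count"`.
#' @return a [measure_estimate()] named `"nri_t"` with the movement-group
#'   shares and class components in `components`.
#' @export
nri_t <- function(pairs, horizon, cutoffs = NULL, w = 0.5,
                  estimator = c("km", "count")) {
  estimator <- match.arg(estimator)
  if (is.null(pairs$time)) {
    pi_error("'pairs' must carry observed times", "predincr_invalid_input")
  }
  if (w < 0 || w > 1) {
    pi_error("'w' must lie in [0, 1]", "predincr_invalid_input")
  }
  if (is.null(cutoffs)) {
    up <- pairs$p_new > pairs$p_old
    down <- pairs$p_new < pairs$p_old
  } else {
    co <- risk_category(pairs$p_old, cutoffs)
    cn <- risk_category(pairs$p_new, cutoffs)
    up <- cn > co
    down <- cn < co
  }
  res <- nri_t_core(pairs$y, pairs$time, up, down, horizon, w, estimator)
  measure_estimate("nri_t", res$value,
                   n_events = sum(pairs$y == 1),
                   n_nonevents = sum(pairs$y == 0),
                   components = res[-1L],
                   metadata = list(horizon = horizon, cutoffs = cutoffs,
                                   w = w, estimator = estimator))
}

#' Explained variation R^2(t) of a survival model
#'
#' `R^2(t) = Var(S(t|Z)) / (S(t) (1 - S(t)))`: the sample variance (n - 1
#' divisor) of the per-subject model-based survival probabilities at the
#' horizon, scaled by the binomial variance of the event-by-t indicator with
#' `S(t)` estimated by Kaplan-Meier. Bounded on `[0, 1]` in theory; a value
#' numerically above 1 is clipped with a warning (the raw value is kept in
#' the `"raw"` attribute).
#'
#' @param surv_probs per-subject predicted survival probabilities `S(t|Z)`.
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param horizon evaluation time t.
#' @return `R^2(t)`, a scalar in `[0, 1]`.
#' @export
r_squared_t <- function(surv_probs, time, event, horizon) {
  if (any(surv_probs < 0 | surv_probs > 1)) {
    pi_error("survival probabilities must lie in [0, 1]",
             "predincr_invalid_input")
  }
  s_t <- km_survival(kaplan_meier(time, event), horizon)
  if (s_t <= 0 || s_t >= 1) {
    pi_error("Kaplan-Meier survival at the horizon is degenerate",
             "predincr_degenerate")
  }
  r2 <- var(surv_probs) / (s_t * (1 - s_t))
  if (r2 > 1) {
    warning("R^2(t) numerically exceeds 1 (", signif(r2, 5),
            "); reporting the clipped value")
    return(structure(1, raw = r2))
  }
  r2
}

#' Survival integrated discrimination improvement IDI(t)
#'
#' `IDI(t) = R^2(t)_new - R^2(t)_old`, the change in the proportion of
#' variance of the event-by-t indicator explained by the model.
#'
#' @param pairs a [risk_pairs()] data frame carrying `time` (predictions are
#'   event probabilities; survival probabilities are their complement).
#' @param horizon evaluation time t.
#' @return a [measure_estimate()] named `"idi_t"` with components `r2_new`,
#'   `r2_old`.
#' @export
idi_t <- function(pairs, horizon) {
  if (is.null(pairs$time)) {
    pi_error("'pairs' must carry observed times", "predincr_invalid_input")
  }
  r2_new <- r_squared_t(1 - pairs$p_new, pairs$time, pairs$y, horizon)
  r2_old <- r_squared_t(1 - pairs$p_old, pairs$time, pairs$y, horizon)
  measure_estimate("idi_t", as.numeric(r2_new) - as.numeric(r2_old),
                   n_events = sum(pairs$y == 1),
                   n_nonevents = sum(pairs$y == 0),
                   components = list(r2_new = as.numeric(r2_new),
                                     r2_old = as.numeric(r2_old)),
                   metadata = list(horizon = horizon))
}
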
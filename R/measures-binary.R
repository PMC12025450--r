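#' Named measure estimate
#'
#' Container for a point estimate with optional asymptotic standard error and
#' the quantities entering it.
#'
#' @param name measure name.
#' @param value point estimate.
#' @param se asymptotic standard error, or `NA` when no formula exists.
#' @param n_events,n_nonevents class sizes.
#' @param components named list of component values (e.g. eNRI / neNRI).
#' @param metadata named list (cutoffs, horizon, ...).
#' @return an object of class `measure_estimate`.
#' @export
measure_estimate <- function(name, value, se = NA_real_,
                             n_events = NA_integer_,
                             n_nonevents = NA_integer_,
                             components = list(), metadata = list()) {
  structure(list(name = name, value = value, se = se,
                 n_events = n_events, n_nonevents = n_nonevents,
                 components = components, metadata = metadata),
            class = "measure_estimate")
}

#' @export
print.measure_estimate <- function(x, ...) {
  cat(x$name, ": ", signif(x$value, 5), sep = "")
  if (is.finite(x$se)) cat("  (asymptotic SE ", signif(x$se, 5), ")", sep = "")
  cat("\n")
  if (length(x$components)) {
    comps <- unlist(x$components)
    cat("  components:",
        paste(names(comps), signif(comps, 5), sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

check_two_classes <- function(y) {
  if (sum(y == 1) == 0L || sum(y == 0) == 0L) {
    pi_error("both events and nonevents are required",
             "predincr_single_class")
  }
}

#' C-statistic (Mann-Whitney AUC estimator)
#'
#' Proportion of (nonevent, event) pairs where the event has the higher
#' predicted risk, with 0.5 credit for ties. Invariant under strictly
#' increasing transformations of the risks.
#'
#' @param risk numeric risk scores or probabilities.
#' @param y 0/1 event indicators.
#' @return the C-statistic in `[0, 1]`.
#' @examples
#' c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)) # 0.75
#' @export
c_statistic <- function(risk, y) {
  stopifnot(length(risk) == length(y))
  check_two_classes(y)
  .cstat_cpp(as.numeric(risk), as.integer(y))
}

# DeLong structural components via midranks: V10 for events, V01 for
# nonevents; mean(V10) = mean(V01) = AUC.
delong_components <- function(risk, y) {
  ev <- y == 1
  r_all <- rank(risk, ties.method = "average")
  v10 <- (r_all[ev] - rank(risk[ev], ties.method = "average")) / sum(!ev)
  v01 <- 1 - (r_all[!ev] - rank(risk[!ev], ties.method = "average")) / sum(ev)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delta_auc_core <- function(y, p_old, p_new, need_se = TRUE) {
  new <- delong_components(p_new, y)
  old <- delong_components(p_old, y)
  value <- new$auc - old$auc
  se <- NA_real_
  if (need_se) {
    n1 <- length(new$v10); n0 <- length(new$v01)
    v <- 0
    if (n1 > 1L) v <- v + var(new$v10 - old$v10) / n1
    if (n0 > 1L) v <- v + var(new$v01 - old$v01) / n0
    se <- sqrt(v)
  }
  list(value = value, se = se, auc_new = new$auc, auc_old = old$auc)
}

#' Change in AUC with the DeLong standard error
#'
#' `C(p_new) - C(p_old)` on the same subjects, with the standard error from
#' the DeLong structural-component estimate of the covariance of the two
#' paired C-statistics, `SE = sqrt((1,-1) S (1,-1)')`.
#'
#' @param pairs a [risk_pairs()] data frame.
#' @return a [measure_estimate()] named `"delta_auc"` with components
#'   `auc_new`, `auc_old`.
#' @export
delta_auc <- function(pairs) {
  check_two_classes(pairs$y)
  res <- delta_auc_core(pairs$y, pairs$p_old, pairs$p_new)
  measure_estimate("delta_auc", res$value, res$se,
                   n_events = sum(pairs$y == 1),
                   n_nonevents = sum(pairs$y == 0),
                   components = list(auc_new = res$auc_new,
                                     auc_old = res$auc_old))
}

#' Default risk-category cutoffs
#'
#' For two categories the single cutoff is the event rate. For three
#' categories the bands are `[0, 0.05), [0.05, 0.20), [0.20, 1]` when the
#' event rate is below 0.3 and `[0, 0.40), [0.40, 0.60), [0.60, 1]`
#' otherwise (the conventional low/high-incidence banding).
#'
#' @param event_rate marginal event rate.
#' @param categories 2 or 3.
#' @return numeric vector of interior cutoffs.
#' @export
default_cutoffs <- function(event_rate, categories = 2) {
  if (categories == 2) return(event_rate)
  if (categories == 3) {
    return(if (event_rate < 0.3) c(0.05, 0.20) else c(0.40, 0.60))
  }
  pi_error("'categories' must be 2 or 3", "predincr_invalid_input")
}

risk_category <- function(p, cutoffs) {
  # half-open bands [low, high)
  findInterval(p, cutoffs) + 1L
}

#' Reclassification table
#'
#' Cross-tabulates old-model vs new-model risk categories separately for
#' events and nonevents, with per-class up/down/same movement tallies.
#' Categories are the half-open intervals `[low, high)` implied by the
#' interior cutoffs.
#'
#' @param pairs a [risk_pairs()] data frame.
#' @param cutoffs strictly increasing interior cutoffs within (0, 1).
#' @return an object of class `reclass_table`.
#' @export
reclassify <- function(pairs, cutoffs) {
  if (length(cutoffs) == 0L) {
    pi_error("at least one cutoff is required", "predincr_invalid_input")
  }
  if (is.unsorted(cutoffs, strictly = TRUE) ||
      any(cutoffs <= 0 | cutoffs >= 1)) {
    pi_error("cutoffs must be strictly increasing within (0, 1)",
             "predincr_invalid_input")
  }
  k <- length(cutoffs) + 1L
  cat_old <- risk_category(pairs$p_old, cutoffs)
  cat_new <- risk_category(pairs$p_new, cutoffs)
  lv <- seq_len(k)
  tab <- function(sel) {
    table(factor(cat_old[sel], levels = lv),
          factor(cat_new[sel], levels = lv), dnn = c("old", "new"))
  }
  ev <- pairs$y == 1
  moves <- function(sel) {
    c(up = sum(cat_new[sel] > cat_old[sel]),
      down = sum(cat_new[sel] < cat_old[sel]),
      same = sum(cat_new[sel] == cat_old[sel]))
  }
  structure(list(cutoffs = cutoffs,
                 events = tab(ev), nonevents = tab(!ev),
                 moves_events = moves(ev), moves_nonevents = moves(!ev),
                 n_events = sum(ev), n_nonevents = sum(!ev)),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat("Reclassification table (cutoffs:",
      paste(x$cutoffs, collapse = ", "), ")\n")
  cat("Events (n =", x$n_events, "):\n"); print(x$events)
  cat("Nonevents (n =", x$n_nonevents, "):\n"); print(x$nonevents)
  invisible(x)
}

# shared NRI algebra: class-wise net movement proportions and their SEs
nri_from_props <- function(up1, down1, up0, down0, n1, n0, name, metadata) {
  enri <- up1 - down1
  nenri <- down0 - up0
  se_enri <- sqrt((up1 + down1) / n1 - (up1 - down1)^2 / n1)
  se_nenri <- sqrt((down0 + up0) / n0 - (down0 - up0)^2 / n0)
  measure_estimate(name, enri + nenri,
                   se = sqrt(se_enri^2 + se_nenri^2),
                   n_events = n1, n_nonevents = n0,
                   components = list(enri = enri, nenri = nenri,
                                     se_enri = se_enri, se_nenri = se_nenri),
                   metadata = metadata)
}

#' Categorical net reclassification improvement
#'
#' `NRI = [P(up|Y=1) - P(down|Y=1)] + [P(down|Y=0) - P(up|Y=0)]`, estimated
#' from the reclassification table, with the standard asymptotic standard
#' errors for the event component (eNRI), the nonevent component (neNRI) and
#' their sum.
#'
#' @param x a `reclass_table`, or a [risk_pairs()] data frame (in which case
#'   `cutoffs` is required).
#' @param cutoffs interior category cutoffs (used when `x` is `risk_pairs`).
#' @return a [measure_estimate()] named `"nri_cat"` with `enri`, `nenri` and
#'   their SEs as components.
#' @export
nri_categorical <- function(x, cutoffs = NULL) {
  if (inherits(x, "risk_pairs")) x <- reclassify(x, cutoffs)
  stopifnot(inherits(x, "reclass_table"))
  n1 <- x$n_events; n0 <- x$n_nonevents
  if (n1 == 0L || n0 == 0L) {
    pi_error("both events and nonevents are required",
             "predincr_single_class")
  }
  me <- x$moves_events / n1
  mn <- x$moves_nonevents / n0
  nri_from_props(me[["up"]], me[["down"]], mn[["up"]], mn[["down"]],
                 n1, n0, "nri_cat", list(cutoffs = x$cutoffs))
}

#' Continuous net reclassification improvement (NRI > 0)
#'
#' The category-free NRI: any strict increase in predicted risk counts as
#' upward movement, any strict decrease as downward movement; exact ties
#' count as neither. Standard errors follow the same algebra as the
#' categorical NRI with risk-comparison proportions.
#'
#' @param pairs a [risk_pairs()] data frame.
#' @return a [measure_estimate()] named `"nri_gt0"`.
#' @export
nri_continuous <- function(pairs) {
  check_two_classes(pairs$y)
  ev <- pairs$y == 1
  up <- pairs$p_new > pairs$p_old
  down <- pairs$p_new < pairs$p_old
  n1 <- sum(ev); n0 <- sum(!ev)
  nri_from_props(mean(up[ev]), mean(down[ev]),
                 mean(up[!ev]), mean(down[!ev]),
                 n1, n0, "nri_gt0", list())
}

#' Integrated discrimination improvement
#'
#' The difference in discrimination slopes,
#' `IDI = (mean p_new - mean p_old | events) -
#' (mean p_new - mean p_old | nonevents)`, with the standard error combining
#' the class-wise standard errors of the per-subject paired differences
#' `p_new - p_old` (sample variance, n - 1 divisor).
#'
#' @param pairs a [risk_pairs()] data frame.
#' @return a [measure_estimate()] named `"idi"`.
#' @export
idi <- function(pairs) {
  check_two_classes(pairs$y)
  ev <- pairs$y == 1
  d <- pairs$p_new - pairs$p_old
  n1 <- sum(ev); n0 <- sum(!ev)
  se1 <- if (n1 > 1L) var(d[ev]) / n1 else 0
  se0 <- if (n0 > 1L) var(d[!ev]) / n0 else 0
  measure_estimate("idi", mean(d[ev]) - mean(d[!ev]),
                   se = sqrt(se1 + se0),
                   n_events = n1, n_nonevents = n0,
                   components = list(mean_diff_events = mean(d[ev]),
                                     mean_diff_nonevents = mean(d[!ev])))
}
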
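# Independent brute-force oracles: deliberately naive O(n^2) double loops,
# kept free of any code shared with the implementation.

brute_cstat <- function(risk, y) {
  ev <- which(y == 1); ne <- which(y == 0)
  s <- 0
  for (i in ne) for (j in ev) {
    s <- s + if (risk[i] < risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
  }
  s / (length(ev) * length(ne))
}

# DeLong SE of AUC(p_new) - AUC(p_old) from explicitly enumerated structural
# components
brute_delong_se <- function(y, p_old, p_new) {
  ev <- which(y == 1); ne <- which(y == 0)
  n1 <- length(ev); n0 <- length(ne)
  psi <- function(a, b) ifelse(a < b, 1, ifelse(a == b, 0.5, 0))
  comp <- function(p) {
    v10 <- vapply(ev, function(j) mean(psi(p[ne], p[j])), numeric(1))
    v01 <- vapply(ne, function(i) mean(psi(p[i], p[ev])), numeric(1))
    list(v10 = v10, v01 = v01)
  }
  cn <- comp(p_new); co <- comp(p_old)
  v1 <- if (n1 > 1) var(cn$v10 - co$v10) / n1 else 0
  v0 <- if (n0 > 1) var(cn$v01 - co$v01) / n0 else 0
  sqrt(v1 + v0)
}

# Harrell's overall C with the earlier-time-must-be-an-event usable rule and
# 0.5 credit for prediction ties
brute_overall_c <- function(risk, time, event, tie_credit = 0.5) {
  n <- length(risk)
  credit <- 0; usable <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (event[a] != 1) next
    usable <- usable + 1
    credit <- credit +
      if (risk[a] > risk[b]) 1 else if (risk[a] == risk[b]) tie_credit else 0
  }
  list(c = credit / usable, usable = usable)
}

# product-limit estimate at a single time by explicit iteration
brute_km_at <- function(time, event, t0) {
  s <- 1
  for (u in sort(unique(time[time <= t0]))) {
    d <- sum(time == u & event == 1)
    r <- sum(time >= u)
    s <- s * (1 - d / r)
  }
  s
}

# survival NRI(t) via survival::survfit subgroup curves and the Bayes
# decomposition (independent route to the package's Kaplan-Meier internals)
survfit_nri_t <- function(pairs, horizon, cutoffs = NULL) {
  km_p <- function(sel) {
    if (!any(sel)) return(0)
    sf <- survival::survfit(survival::Surv(pairs$time[sel], pairs$y[sel]) ~ 1)
    1 - min(summary(sf, times = horizon, extend = TRUE)$surv)
  }
  if (is.null(cutoffs)) {
    up <- pairs$p_new > pairs$p_old
    down <- pairs$p_new < pairs$p_old
  } else {
    co <- findInterval(pairs$p_old, cutoffs)
    cn <- findInterval(pairs$p_new, cutoffs)
    up <- cn > co; down <- cn < co
  }
  p <- km_p(rep(TRUE, nrow(pairs)))
  p1u <- km_p(up); p1d <- km_p(down)
  pu <- mean(up); pd <- mean(down)
  (p1u * pu - p1d * pd) / p +
    ((1 - p1d) * pd - (1 - p1u) * pu) / (1 - p)
}

# construct a bootstrap_dist object directly for interval-arithmetic tests
make_dist <- function(estimates, point, ses = NULL, point_se = NA_real_,
                      B = length(estimates), measure = "toy") {
  structure(list(measure = measure, estimates = estimates, inner_ses = ses,
                 point_estimate = point, point_se = point_se,
                 b_requested = B, b_valid = length(estimates),
                 failures = table(character(0)), usable = TRUE),
            class = "bootstrap_dist")
}

# small random paired-prediction fixtures
random_pairs <- function(n, seed, rate = 0.4, ties = FALSE) {
  set.seed(seed)
  y <- rbinom(n, 1, rate)
  if (all(y == y[1])) y[1] <- 1 - y[1]
  p_old <- plogis(rnorm(n) + 0.8 * y)
  p_new <- plogis(rnorm(n) + 1.3 * y)
  if (ties) {
    p_old <- round(p_old, 1); p_new <- round(p_new, 1)
  }
  risk_pairs(y, p_old, p_new)
}

random_survival_pairs <- function(n, seed, cens_rate = 0.3) {
  set.seed(seed)
  u <- rexp(n)
  cens <- rexp(n, cens_rate)
  time <- pmin(u, cens)
  y <- as.integer(u <= cens)
  risk_pairs(y, plogis(rnorm(n)), plogis(rnorm(n)), time = time)
}
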
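test_that("asymptotic intervals use the normal quantile", {
  ci <- asymptotic_ci(list(value = 0, se = 1), alpha = 0.025)
  expect_equal(ci$lower, -qnorm(0.975))
  expect_equal(ci$upper, qnorm(0.975))
  z <- asymptotic_ci(list(value = 0.3, se = 0))
  expect_equal(z$width, 0)
  expect_equal(z$lower, 0.3)
  # survival measures carry no SE formula
  pr <- random_survival_pairs(50, seed = 1)
  expect_error(asymptotic_ci(delta_c(pr)),
               class = "predincr_unsupported_method")
})

test_that("asymptotic coverage for a Gaussian mean matches the exact law", {
  # harness self-test: with the z quantile and an estimated SD, coverage of
  # the mean of n = 50 normals is exactly 2*pt(z, 49) - 1
  set.seed(2)
  reps <- 1e4; n <- 50
  x <- matrix(rnorm(reps * n), n)
  m <- colMeans(x)
  se <- sqrt((colSums(x^2) - n * m^2) / (n - 1) / n)
  covered <- vapply(seq_len(reps), function(i) {
    ci <- asymptotic_ci(list(value = m[i], se = se[i]), 0.025)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  exact <- 2 * stats::pt(qnorm(0.975), n - 1) - 1
  expect_lt(abs(mean(covered) - exact), 3 * sqrt(exact * (1 - exact) / reps))
})

test_that("percentile endpoints follow the order-statistic rule", {
  d <- make_dist(as.numeric(1:1000), point = 500)
  ci <- percentile_ci(d, alpha = 0.025)
  # h = (n + 1) p interpolation: 1001 * 0.025 = 25.025
  expect_equal(ci$lower, 25.025)
  expect_equal(ci$upper, 975.975)
  expect_equal(ci$lower,
               unname(quantile(d$estimates, 0.025, type = 6)))
  cst <- make_dist(rep(1.5, 200), point = 1.5)
  expect_equal(percentile_ci(cst)$width, 0)
})

test_that("percentile intervals are transform-equivariant at exact ranks", {
  set.seed(3)
  x <- rnorm(999)   # (n + 1) * 0.025 = 25: no interpolation
  d <- make_dist(x, point = 0)
  dg <- make_dist(exp(x), point = 1)
  expect_equal(percentile_ci(dg)$lower, exp(percentile_ci(d)$lower))
  expect_equal(percentile_ci(dg)$upper, exp(percentile_ci(d)$upper))
})

test_that("BC reduces to percentile at zero median bias and shifts when
           biased", {
  set.seed(4)
  x <- rnorm(500)
  d0 <- make_dist(x, point = median(x))  # exactly half below
  expect_equal(bc_ci(d0)$lower, percentile_ci(d0)$lower)
  expect_equal(bc_ci(d0)$upper, percentile_ci(d0)$upper)
  # 40% of replicates below the point estimate: closed-form adjustment
  xs <- sort(rexp(200))
  point <- xs[81] - 1e-9
  d <- make_dist(xs, point = point)
  z0 <- qnorm(mean(xs < point))
  lev <- pnorm(2 * z0 + qnorm(c(0.025, 0.975)))
  expect_equal(bc_ci(d)$lower, unname(quantile(xs, lev[1], type = 6)))
  expect_equal(bc_ci(d)$upper, unname(quantile(xs, lev[2], type = 6)))
  all_above <- make_dist(xs, point = xs[1] - 1)
  expect_error(bc_ci(all_above), class = "predincr_degenerate")
})

test_that("BCa reduces to percentile with zero correction and matches hand
           arithmetic", {
  set.seed(5)
  x <- rnorm(400)
  d <- make_dist(x, point = median(x))
  jack_sym <- rep(c(-1, 1), 25) + 5      # symmetric influence: a = 0
  expect_equal(bca_ci(d, jack_sym)$lower, percentile_ci(d)$lower)
  expect_equal(bca_ci(d, jack_sym)$upper, percentile_ci(d)$upper)
  # skewed jackknife: follow the acceleration formula independently
  jack <- c(rexp(30), 8)
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  z0 <- qnorm(mean(x < median(x)))
  zq <- qnorm(c(0.025, 0.975))
  lev <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- bca_ci(d, jack)
  expect_equal(ci$lower, unname(quantile(x, lev[1], type = 6)))
  expect_equal(ci$upper, unname(quantile(x, lev[2], type = 6)))
  expect_error(bca_ci(d, rep(2, 40)), class = "predincr_degenerate")
})

test_that("bootstrap-t studentizes with the replicate SEs", {
  set.seed(6)
  est <- rnorm(300, 1, 0.2)
  ses <- runif(300, 0.15, 0.25)
  d <- make_dist(est, point = 1, ses = ses, point_se = 0.2)
  tq <- quantile((est - 1) / ses, c(0.025, 0.975), type = 6)
  ci <- bootstrap_t_ci(d)
  expect_equal(ci$lower, unname(1 - tq[2] * 0.2))
  expect_equal(ci$upper, unname(1 - tq[1] * 0.2))
  # symmetric pivots with equal SEs give an interval symmetric about theta
  sym <- make_dist(1 + c(-rev(seq_len(150)), seq_len(150)) / 100,
                   point = 1, ses = rep(0.5, 300), point_se = 0.5)
  cis <- bootstrap_t_ci(sym)
  expect_equal(cis$upper - 1, 1 - cis$lower)
  expect_error(bootstrap_t_ci(make_dist(est, 1)),
               class = "predincr_unsupported_method")
  bad <- make_dist(est, 1, ses = c(rep(0, 30), ses[-(1:30)]), point_se = 0.2)
  expect_error(bootstrap_t_ci(bad), class = "predincr_unusable_bootstrap")
})

test_that("bootstrap-t coverage for a Gaussian mean is near nominal", {
  # textbook benchmark: mean of n = 50 normals, se = sd/sqrt(n)
  set.seed(7)
  reps <- 400; n <- 50; B <- 199
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n)
    bm <- colMeans(matrix(x[idx], n))
    bs <- apply(matrix(x[idx], n), 2, sd) / sqrt(n)
    d <- make_dist(bm, point = mean(x), ses = bs,
                   point_se = sd(x) / sqrt(n))
    ci <- bootstrap_t_ci(d)
    covered[r] <- ci$lower <= 0 && 0 <= ci$upper
  }
  expect_lt(abs(mean(covered) - 0.95), 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("hybrid intervals reflect the percentile endpoints exactly", {
  for (s in 1:20) {
    set.seed(s)
    d <- make_dist(rexp(150), point = 1)
    p <- percentile_ci(d); h <- hybrid_ci(d)
    expect_equal(h$lower, 2 * 1 - p$upper)
    expect_equal(h$upper, 2 * 1 - p$lower)
    expect_lte(h$lower, h$upper)
  }
  # right-skewed distribution shifts the hybrid interval left
  d <- make_dist(rexp(500), point = median(rexp(500)))
  expect_lt(hybrid_ci(d)$upper, percentile_ci(d)$upper)
})

test_that("all interval methods are ordered on random distributions", {
  for (s in 1:25) {
    set.seed(700 + s)
    x <- rnorm(200, sd = runif(1, 0.1, 3)) + rexp(200) * rbinom(1, 1, 0.5)
    point <- sample(x, 1)
    d <- make_dist(x, point = point, ses = runif(200, 0.5, 1), point_se = 1)
    for (ci in list(percentile_ci(d), hybrid_ci(d), bootstrap_t_ci(d))) {
      expect_lte(ci$lower, ci$upper)
    }
    if (mean(x < point) > 0 && mean(x < point) < 1) {
      expect_lte(bc_ci(d)$lower, bc_ci(d)$upper)
    }
  }
})

test_that("the resampling engine is deterministic and flags degeneracy", {
  coh <- generate_binary_cohort(binary_design(200, 0.3), seed = 8)
  b1 <- bootstrap_measures(coh, 1, c(1, 5), c("delta_auc", "idi"), B = 120,
                           seed = 99)
  b2 <- bootstrap_measures(coh, 1, c(1, 5), c("delta_auc", "idi"), B = 120,
                           seed = 99)
  expect_identical(b1$idi$estimates, b2$idi$estimates)
  expect_identical(b1$delta_auc$estimates, b2$delta_auc$estimates)
  expect_equal(b1$idi$b_valid, 120)

  # identical nested models: the measure is constant at zero
  b0 <- bootstrap_measures(coh, 1, 1, "idi", B = 120, seed = 99)
  expect_true(all(b0$idi$estimates == 0))

  # one event among 30 subjects: resamples lose the event class often
  rare <- list(y = c(1, rep(0, 29)),
               x = cbind(x1 = rnorm(30)), framework = "binary")
  class(rare) <- "cohort"
  br <- bootstrap_measures(rare, 1, 1, "idi", B = 150, seed = 5)
  expect_false(br$idi$usable)
  expect_gt(sum(br$idi$failures), 0)
  expect_error(percentile_ci(br$idi),
               class = "predincr_unusable_bootstrap")
  # stratified resampling preserves the class split and stays usable
  bs <- bootstrap_measures(rare, 1, 1, "idi", B = 150, seed = 5,
                           stratified = TRUE)
  expect_true(bs$idi$usable)
  expect_gt(bs$idi$b_valid, br$idi$b_valid)
  expect_error(bootstrap_measures(coh, 1, c(1, 5), "idi", B = 50, seed = 1),
               class = "predincr_invalid_input")
})

test_that("bootstrap means track the point estimate and endpoints stabilise
           in B", {
  coh <- generate_binary_cohort(binary_design(300, 0.3), seed = 14)
  b <- bootstrap_measures(coh, 1, c(1, 5), "idi", B = 800, seed = 3)
  dist <- b$idi
  boot_se <- sd(dist$estimates)
  expect_lt(abs(mean(dist$estimates) - dist$point_estimate), 3 * boot_se)
  small <- dist; small$estimates <- dist$estimates[1:200]
  small$b_valid <- 200L; small$b_requested <- 200L
  q_small <- percentile_ci(small)
  q_full <- percentile_ci(dist)
  expect_lt(abs(q_small$lower - q_full$lower), 4 * boot_se / sqrt(200) * 10)
  expect_lt(abs(q_small$upper - q_full$upper), 4 * boot_se / sqrt(200) * 10)
})

test_that("jackknife estimates feed BCa end to end", {
  coh <- generate_binary_cohort(binary_design(120, 0.4), seed = 15)
  jk <- jackknife_estimates(coh, 1, c(1, 5), "idi")
  expect_length(jk, 120)
  expect_true(all(is.finite(jk)))
  b <- bootstrap_measures(coh, 1, c(1, 5), "idi", B = 200, seed = 16)
  ci <- bca_ci(b$idi, jk)
  expect_lte(ci$lower, ci$upper)
})
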
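test_that("C-statistic matches enumeration on canonical cases", {
  expect_equal(c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_equal(c_statistic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(c_statistic(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(c_statistic(1:4, rep(1, 4)), class = "predincr_single_class")
})

test_that("C-statistic equals the brute-force pair count on random inputs", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    risk <- round(runif(n), sample(1:2, 1))  # induce ties
    expect_equal(c_statistic(risk, y), brute_cstat(risk, y))
  }
})

test_that("rank measures are invariant under increasing transforms", {
  pr <- random_pairs(80, seed = 5)
  g <- function(p) plogis(3 * qlogis(p) + 1)  # strictly increasing
  pr2 <- risk_pairs(pr$y, g(pr$p_old), g(pr$p_new))
  expect_equal(c_statistic(pr2$p_new, pr2$y), c_statistic(pr$p_new, pr$y))
  expect_equal(delta_auc(pr2)$value, delta_auc(pr)$value)
  expect_equal(nri_continuous(pr2)$value, nri_continuous(pr)$value)
})

test_that("DeLong SE matches the brute-force structural components", {
  # degenerate case: identical predictions give a zero-variance contrast
  pr0 <- random_pairs(30, seed = 1)
  pr0$p_new <- pr0$p_old
  d0 <- delta_auc(pr0)
  expect_equal(d0$value, 0)
  expect_equal(d0$se, 0)
  for (s in 1:50) {
    pr <- random_pairs(sample(6:8, 1), seed = 100 + s)
    expect_equal(delta_auc(pr)$se,
                 brute_delong_se(pr$y, pr$p_old, pr$p_new),
                 tolerance = 1e-10)
  }
  # larger input against the independent pROC implementation
  pr <- random_pairs(150, seed = 6)
  da <- delta_auc(pr)
  rt <- pROC::roc.test(pROC::roc(pr$y, pr$p_new, quiet = TRUE),
                       pROC::roc(pr$y, pr$p_old, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(da$se, abs(da$value / unname(rt$statistic)),
               tolerance = 1e-10)
})

test_that("reclassification uses half-open categories", {
  cuts <- c(0.05, 0.20)
  pr <- risk_pairs(y = c(1, 1, 0, 0, 1),
                   p_old = c(0.04, 0.05, 0.19, 0.20, 0.50),
                   p_new = c(0.04, 0.05, 0.19, 0.20, 0.50))
  tab <- reclassify(pr, cuts)
  expect_equal(unname(tab$moves_events), c(0, 0, 3))
  # boundary values fall in the upper band: [0.05, 0.20) and [0.20+)
  expect_equal(unname(diag(tab$events) + diag(tab$nonevents)),
               c(1, 2, 2))

  one_up <- reclassify(risk_pairs(1, 0.05, 0.15), 0.10)
  expect_equal(unname(one_up$moves_events[["up"]]), 1)
  expect_error(reclassify(pr, numeric(0)), class = "predincr_invalid_input")
  expect_error(reclassify(pr, c(0.3, 0.2)), class = "predincr_invalid_input")
})

test_that("categorical NRI reproduces the hand-worked table", {
  # events: 3 up, 1 down of 10; nonevents: 2 down, 1 up of 10; cutoff 0.5
  p_old <- c(rep(0.4, 3), 0.6, rep(0.4, 6),  # events
             rep(0.6, 2), 0.4, rep(0.4, 7))  # nonevents
  p_new <- c(rep(0.6, 3), 0.4, rep(0.4, 6),
             rep(0.4, 2), 0.6, rep(0.4, 7))
  pr <- risk_pairs(rep(c(1, 0), each = 10), p_old, p_new)
  est <- nri_categorical(pr, cutoffs = 0.5)
  expect_equal(est$components$enri, 0.2)
  expect_equal(est$components$nenri, 0.1)
  expect_equal(est$value, 0.3)
  expect_equal(est$components$se_enri, sqrt(0.4 / 10 - 0.04 / 10))
  expect_equal(est$components$se_nenri, sqrt(0.029))
  expect_equal(est$se, sqrt(0.036 + 0.029))
})

test_that("NRI attains its extremes and zero fixed points", {
  pr_same <- random_pairs(40, seed = 2)
  pr_same$p_new <- pr_same$p_old
  expect_equal(nri_categorical(pr_same, 0.3)$value, 0)
  expect_equal(nri_continuous(pr_same)$value, 0)
  # every event up, every nonevent down
  y <- rep(c(1, 0), each = 5)
  pr_max <- risk_pairs(y, p_old = ifelse(y == 1, 0.2, 0.8),
                       p_new = ifelse(y == 1, 0.8, 0.2))
  expect_equal(nri_categorical(pr_max, 0.5)$value, 2)
  expect_equal(nri_continuous(pr_max)$value, 2)
})

test_that("continuous NRI reproduces the hand-worked proportions", {
  # events: 3 up, 1 down; nonevents: 4 down, 1 up
  pr <- risk_pairs(c(rep(1, 4), rep(0, 5)),
                   p_old = c(0.3, 0.3, 0.3, 0.5, rep(0.5, 4), 0.3),
                   p_new = c(0.4, 0.5, 0.6, 0.4, rep(0.3, 4), 0.4))
  est <- nri_continuous(pr)
  expect_equal(est$components$enri, 0.5)
  expect_equal(est$components$nenri, 0.6)
  expect_equal(est$value, 1.1)
  expect_equal(est$components$se_enri, sqrt(1 / 4 - 0.25 / 4))
  expect_equal(est$components$se_nenri, sqrt(1 / 5 - 0.36 / 5))
  # an exact tie counts as neither an increase nor a decrease
  pr2 <- risk_pairs(c(pr$y, 1), c(pr$p_old, 0.5), c(pr$p_new, 0.5))
  est2 <- nri_continuous(pr2)
  expect_equal(est2$components$enri, (3 - 1) / 5)
})

test_that("NRI decomposition and SE identities hold on random inputs", {
  for (s in 1:40) {
    pr <- random_pairs(sample(10:60, 1), seed = 200 + s, ties = TRUE)
    for (est in list(nri_categorical(pr, c(0.3, 0.6)), nri_continuous(pr))) {
      expect_equal(est$value, est$components$enri + est$components$nenri,
                   tolerance = 1e-12)
      expect_equal(est$se^2,
                   est$components$se_enri^2 + est$components$se_nenri^2,
                   tolerance = 1e-12)
      expect_true(abs(est$components$enri) <= 1)
      expect_true(abs(est$components$nenri) <= 1)
      expect_true(abs(est$value) <= 2)
    }
  }
})

test_that("IDI equals the change in discrimination slope", {
  pr <- risk_pairs(c(1, 1, 0, 0),
                   p_old = c(0.5, 0.7, 0.3, 0.5),
                   p_new = c(0.6, 0.8, 0.25, 0.45))
  est <- idi(pr)
  expect_equal(est$value, 0.15)
  expect_equal(est$se, 0)  # constant within-class differences
  # independent route: difference of discrimination slopes
  for (s in 1:25) {
    prr <- random_pairs(sample(10:50, 1), seed = 300 + s)
    slope <- function(p) mean(p[prr$y == 1]) - mean(p[prr$y == 0])
    expect_equal(idi(prr)$value, slope(prr$p_new) - slope(prr$p_old),
                 tolerance = 1e-12)
  }
  pr0 <- random_pairs(30, seed = 4)
  pr0$p_new <- pr0$p_old
  z <- idi(pr0)
  expect_equal(z$value, 0)
  expect_equal(z$se, 0)
})

test_that("default cutoffs follow the event rate", {
  expect_equal(default_cutoffs(0.1, 2), 0.1)
  expect_equal(default_cutoffs(0.5, 2), 0.5)
  expect_equal(default_cutoffs(0.1, 3), c(0.05, 0.20))
  expect_equal(default_cutoffs(0.5, 3), c(0.40, 0.60))
})

test_that("compute_measure dispatches to the named estimators", {
  pr <- random_pairs(60, seed = 13, rate = 0.3)
  expect_equal(compute_measure(pr, "idi")$value, idi(pr)$value)
  expect_equal(compute_measure(pr, "nri_gt0")$value, nri_continuous(pr)$value)
  expect_equal(compute_measure(pr, "nri_cat2")$value,
               nri_categorical(pr, mean(pr$y))$value)
  expect_error(compute_measure(pr, "nope"), class = "predincr_invalid_input")
})
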
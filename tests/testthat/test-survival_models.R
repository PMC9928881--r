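test_that("anchor validation rejects impossible anchor combinations", {
  expect_error(survival_anchors(-5, 60, 0.25), "median_months")
  expect_error(survival_anchors(39, 39, 0.25), "differ")
  expect_error(survival_anchors(39, 60, 0), "strictly in")
  expect_error(survival_anchors(39, 60, 1), "strictly in")
  # survival on the wrong side of 0.5 relative to the median
  expect_error(survival_anchors(39, 60, 0.6), "< 0.5")
  expect_error(survival_anchors(39, 20, 0.3), "> 0.5")
})

test_that("closed-form calibration agrees with an independent 2-D optimizer", {
  cases <- list(c(39, 60, 0.25), c(14, 60, 0.05), c(24, 48, 0.30))
  for (cs in cases) {
    fit <- fit_weibull_anchors(survival_anchors(cs[1], cs[2], cs[3]))
    ora <- oracle_fit_weibull(cs[1], cs[2], cs[3])
    expect_lt(ora$objective, 1e-12)
    expect_equal(fit$shape, ora$shape, tolerance = 1e-6)
    expect_equal(fit$scale_months, ora$scale_months, tolerance = 1e-6)
  }
})

test_that("fitted laws reproduce both anchors and the printed parameters", {
  m <- matched_fit()
  expect_equal(survival_at(m, 39), 0.5, tolerance = 1e-12)
  expect_equal(survival_at(m, 60), 0.25, tolerance = 1e-12)
  expect_equal(m$shape, 1.6090, tolerance = 1e-4)
  expect_equal(m$scale_months, 48.98, tolerance = 1e-4)

  u <- unmatched_fit()
  expect_equal(survival_at(u, 14), 0.5, tolerance = 1e-12)
  expect_equal(survival_at(u, 60), 0.05, tolerance = 1e-12)
  expect_equal(u$shape, 1.0058, tolerance = 1e-4)
  expect_equal(u$scale_months, 20.16, tolerance = 1e-3)

  # survival halving at twice the median forces the exponential law
  e <- fit_weibull_anchors(survival_anchors(10, 20, 0.25))
  expect_equal(e$shape, 1, tolerance = 1e-12)
  expect_equal(e$scale_months, 10 / log(2), tolerance = 1e-12)
})

test_that("anchor round-trip holds across a grid of anchor sets", {
  set.seed(11)
  for (i in 1:25) {
    m <- runif(1, 5, 80)
    h <- m * runif(1, 1.2, 4)
    sh <- runif(1, 0.01, 0.45)
    fit <- fit_weibull_anchors(survival_anchors(m, h, sh))
    expect_lt(abs(survival_at(fit, m) - 0.5), 1e-9)
    expect_lt(abs(survival_at(fit, h) - sh), 1e-9)
  }
})

test_that("calibration is scale-equivariant in time", {
  base <- fit_weibull_anchors(survival_anchors(14, 60, 0.05))
  for (c_ in c(0.5, 2, 12)) {
    scaled <- fit_weibull_anchors(survival_anchors(14 * c_, 60 * c_, 0.05))
    expect_equal(scaled$shape, base$shape, tolerance = 1e-12)
    expect_equal(scaled$scale_months, base$scale_months * c_, tolerance = 1e-10)
  }
})

test_that("survival evaluation behaves as a survival function", {
  m <- matched_fit()
  expect_identical(survival_at(m, 0), 1)
  expect_error(survival_at(m, -1), "negative")
  t <- seq(0, 300, by = 1)
  expect_true(all(diff(survival_at(m, t)) < 0))
  expect_equal(survival_at(weibull_survival(1, 14.427), 10), 0.5,
               tolerance = 1e-4)
})

test_that("mean survival matches the closed form and numerical integration", {
  expect_equal(mean_months(weibull_survival(1, 20)), 20)
  for (model in list(matched_fit(), unmatched_fit())) {
    auc <- oracle_trapezoid_auc(function(t) survival_at(model, t), 3000)
    expect_equal(mean_months(model), auc, tolerance = 1e-6)
  }
})

test_that("restricted mean survival is consistent with quadrature oracles", {
  exp20 <- weibull_survival(1, 20)
  expect_equal(rmst_months(exp20, 20), 20 * (1 - exp(-1)), tolerance = 1e-8)
  expect_equal(rmst_months(exp20, 10000), 20, tolerance = 1e-6)
  m <- matched_fit()
  expect_equal(rmst_months(m, 60),
               oracle_trapezoid_auc(function(t) survival_at(m, t), 60),
               tolerance = 1e-7)
  expect_lte(rmst_months(m, 60), min(60, mean_months(m)))
  expect_error(rmst_months(m, 0), "positive")
})

test_that("inverse-transform sampling is deterministic and unbiased", {
  m <- matched_fit()
  expect_identical(sample_months(m, 0, seed = 1), numeric(0))
  expect_identical(sample_months(m, 5, seed = 7), sample_months(m, 5, seed = 7))

  x <- sample_months(m, 1e6, seed = 1)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean_months(m)), 3 * se)

  # empirical survival at the anchor times matches the anchor probabilities
  x5 <- sample_months(m, 1e5, seed = 2)
  for (anchor in list(c(39, 0.5), c(60, 0.25))) {
    p <- anchor[2]
    emp <- mean(x5 > anchor[1])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / length(x5)))
  }
})

test_that("quantile evaluation inverts the survival curve", {
  m <- unmatched_fit()
  u <- c(0.999, 0.5, 0.25, 0.05, 0.001)
  expect_equal(survival_at(m, quantile_months(m, u)), u, tolerance = 1e-12)
  expect_equal(quantile_months(m, 0.5), 14, tolerance = 1e-10)
  expect_error(quantile_months(m, 0), "survival probabilities")
})

test_that("mean override rescales the law while keeping its shape", {
  m <- matched_fit()
  m2 <- override_mean(m, 54.6)
  expect_equal(m2$shape, m$shape)
  expect_equal(mean_months(m2), 54.6, tolerance = 1e-10)
  expect_error(override_mean(m, -1), "positive")
})
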
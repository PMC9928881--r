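test_that("credible interval matches the inclusive percentile formula", {
  expect_equal(credible_interval(rep(3.7, 10)), c(3.7, 3.7))
  expect_equal(credible_interval(1:1000), c(25.975, 975.025))
  a <- 2.5; b <- 11.5
  expect_equal(credible_interval(c(a, b)),
               c(a + 0.025 * (b - a), a + 0.975 * (b - a)))
  expect_error(credible_interval(numeric(0)), "at least one")
})

test_that("life-year gains accrue only to identified driver-positive patients", {
  co <- generate_cohort(20000, seed = 8)
  co <- allocate_tests(co, testing_mix(0.20, 0.65, 0.15), seed = 8)
  co <- detect(co)
  co <- patient_lyg_months(co, matched_fit(), unmatched_fit(), seed = 8)
  identified <- co$detected & co$driver_gene != "NONE"
  expect_true(all(co$lyg_months[!identified] == 0))
  expect_true(all(co$lyg_months >= 0))
  expect_gt(mean(co$lyg_months[identified]), 0)
})

test_that("the median-quantile gain is the difference of the two medians", {
  gain_at_median <- quantile_months(matched_fit(), 0.5) -
    quantile_months(unmatched_fit(), 0.5)
  expect_equal(gain_at_median, 39 - 14, tolerance = 1e-9)
})

test_that("the mean per-patient gain matches the difference of means", {
  m <- matched_fit(); u <- unmatched_fit()
  n <- 1e6
  co <- data.frame(
    patient_id = seq_len(n),
    driver_gene = factor(rep("EGFR", n), levels = c(ado_genes(), "NONE")),
    assigned_test = factor(rep("NGS", n), levels = c("NONE", "SGT", "NGS")),
    detected = TRUE
  )
  co <- patient_lyg_months(co, m, u, seed = 31)
  expected <- mean_months(m) - mean_months(u)
  se <- sd(co$lyg_months) / sqrt(n)
  expect_lt(abs(mean(co$lyg_months) - expected), 3 * se)
})

test_that("an untested population yields nothing and an undefined ratio", {
  s <- run_scenario(small_config(mix = testing_mix(1, 0, 0), replicates = 4L))
  expect_equal(s$identified_fraction, 0)
  expect_equal(s$total_lyg_years, 0)
  expect_true(is.na(s$cost_per_lyg_usd))
  a <- analytic_expectation(small_config(mix = testing_mix(1, 0, 0)))
  expect_equal(a$total_lyg_years, 0)
  expect_true(is.na(a$cost_per_lyg_usd))
})

test_that("scenario runs are bit-identical under a fixed seed", {
  cfg <- small_config(n = 2000, replicates = 5L, seed = 99L)
  expect_identical(run_scenario(cfg), run_scenario(cfg))
  cfg2 <- small_config(n = 2000, replicates = 5L, seed = 100L)
  expect_false(identical(run_scenario(cfg)$total_lyg_years,
                         run_scenario(cfg2)$total_lyg_years))
  # the analytic path ignores the seed entirely
  expect_equal(analytic_expectation(cfg), analytic_expectation(cfg2))
})

test_that("closed-form expectations follow the N*q*(mean gap) identity", {
  cfg <- small_config(mix = testing_mix(0.20, 0.80, 0))
  a <- analytic_expectation(cfg)
  gap <- mean_months(cfg$matched_model) - mean_months(cfg$unmatched_model)
  expect_equal(a$identified_fraction, 0.152)
  expect_equal(a$total_lyg_years, cfg$cohort_size * 0.152 * gap / 12)
  full <- analytic_expectation(small_config(mix = testing_mix(0, 0, 1)))
  expect_equal(full$identified_fraction, 0.293)
})

test_that("Monte Carlo means track the analytic oracle", {
  cfg <- small_config(n = 20000, replicates = 30L, seed = 7L)
  s <- run_scenario(cfg)
  a <- analytic_expectation(cfg)
  expect_lt(abs(s$identified_fraction - a$identified_fraction),
            3 * s$identified_fraction_se)
  expect_lt(abs(s$total_lyg_years - a$total_lyg_years), 3 * s$total_lyg_se)
})

test_that("truncating at an RMST horizon shrinks gains consistently", {
  cfg <- small_config(n = 5000, replicates = 5L, rmst_horizon_months = 60)
  cfg_free <- small_config(n = 5000, replicates = 5L)
  expect_lt(run_scenario(cfg)$total_lyg_years,
            run_scenario(cfg_free)$total_lyg_years)
  a <- analytic_expectation(cfg)
  gap <- rmst_months(cfg$matched_model, 60) - rmst_months(cfg$unmatched_model, 60)
  expect_equal(a$total_lyg_years,
               cfg$cohort_size * a$identified_fraction * gap / 12)
})

test_that("the sweep enumerates the NGS grid with derived sub-seeds", {
  cfg <- small_config(n = 1000, replicates = 2L)
  sw <- sweep_scenarios(cfg, step = 0.05, analytic = TRUE)
  expect_equal(nrow(sw), 17)
  expect_equal(sw$ngs_fraction, seq(0, 0.80, by = 0.05))
  expect_true(all(diff(sw$identified_fraction) > 0))
  expect_true(all(diff(sw$total_lyg_years) > 0))
  expect_true(all(diff(sw$testing_cost_usd) < 0))

  expect_equal(nrow(sweep_scenarios(cfg, step = 0.80, analytic = TRUE)), 2)
  expect_error(sweep_scenarios(cfg, step = 0.07), "evenly")

  full <- sweep_scenarios(cfg, step = 0.40, include_full_testing = TRUE,
                          analytic = TRUE)
  expect_equal(full$ngs_fraction, c(0, 0.40, 0.80, 1))
  expect_equal(full$identified_fraction[4], 0.293)
})

test_that("incremental steps rescale to per-10-point increments", {
  # telescoping: the average per-10% increment depends only on the endpoints
  lyg <- seq(38838, 59857, length.out = 9)
  fake <- data.frame(ngs_fraction = seq(0, 0.8, by = 0.1),
                     total_lyg_years = lyg,
                     cost_per_lyg_usd = rep(1000, 9))
  inc <- incremental_per_step(fake, step_size = 0.10)
  expect_equal(unname(inc$average["lyg_per_10pt"]), (59857 - 38838) / 8)
  expect_equal(unname(inc$average["cost_per_lyg_change_per_10pt"]), 0)
  expect_equal(nrow(inc$per_step), 8)

  lin <- data.frame(ngs_fraction = seq(0, 0.8, by = 0.05),
                    total_lyg_years = 100 * seq(0, 0.8, by = 0.05),
                    cost_per_lyg_usd = 5)
  inc2 <- incremental_per_step(lin, step_size = 0.05)
  expect_true(all(abs(inc2$per_step$lyg_per_10pt - 10) < 1e-9))
})

test_that("sub-seed lineage is deterministic and in integer range", {
  s1 <- replicate_seed(1L, 3L, 7L)
  expect_identical(s1, replicate_seed(1L, 3L, 7L))
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_false(replicate_seed(1L, 3L, 8L) == s1)
  expect_false(replicate_seed(2L, 3L, 7L) == s1)
})
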
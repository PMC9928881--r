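#' Scenario configuration
#'
#' Everything needed to run one testing-mix scenario: the cohort size,
#' driver prevalences, testing mix, the two calibrated survival laws,
#' cost inputs, Monte Carlo replicate count and master seed.
#'
#' @param cohort_size Patients per simulated cohort (default 89,000).
#' @param prevalences A [prevalence_table()].
#' @param mix A [testing_mix()].
#' @param matched_model Weibull law for identified patients on matched
#'   targeted therapy (default: calibrated to median 39 months, 5-year
#'   survival 25%).
#' @param unmatched_model Weibull law for patients on standard
#'   chemoimmunotherapy (default: median 14 months, 5-year survival 5%).
#' @param costs A [cost_inputs()].
#' @param replicates Monte Carlo replicates per scenario (default 200).
#' @param seed Master integer seed.
#' @param rmst_horizon_months Optional truncation horizon for life-years;
#'   `NULL` (the default) means untruncated survival.
#' @param panels Gene panels, as from [default_panels()].
#' @param performance A [test_performance()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(cohort_size = 89000,
                            prevalences = prevalence_table(),
                            mix = testing_mix(),
                            matched_model = fit_weibull_anchors(
                              survival_anchors(39, 60, 0.25)),
                            unmatched_model = fit_weibull_anchors(
                              survival_anchors(14, 60, 0.05)),
                            costs = cost_inputs(),
                            replicates = 200,
                            seed = 1,
                            rmst_horizon_months = NULL,
                            panels = default_panels(),
                            performance = test_performance()) {
  stopifnot(inherits(prevalences, "prevalence_table"),
            inherits(mix, "testing_mix"),
            inherits(matched_model, "weibull_survival"),
            inherits(unmatched_model, "weibull_survival"),
            inherits(costs, "cost_inputs"),
            inherits(performance, "test_performance"))
  if (!is.numeric(cohort_size) || length(cohort_size) != 1L || cohort_size < 1)
    stop("cohort_size must be at least 1")
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop("replicates must be at least 1")
  if (!is.null(rmst_horizon_months) &&
      (!is.numeric(rmst_horizon_months) || rmst_horizon_months <= 0))
    stop("rmst_horizon_months must be NULL or a positive time")
  structure(
    list(cohort_size = as.integer(cohort_size), prevalences = prevalences,
         mix = mix, matched_model = matched_model,
         unmatched_model = unmatched_model, costs = costs,
         replicates = as.integer(replicates), seed = as.integer(seed),
         rmst_horizon_months = rmst_horizon_months,
         panels = panels, performance = performance),
    class = "scenario_config")
}

#' Deterministic sub-seed lineage
#'
#' Sub-seed for a given scenario and replicate, derived from the master
#' seed so every scenario and replicate is independently reproducible:
#' (master + 1000003 * scenario_index + 7919 * replicate_index)
#' mod (2^31 - 1).
#'
#' @param master_seed Master integer seed.
#' @param scenario_index Zero-based scenario position in a sweep.
#' @param replicate_index One-based replicate number.
#' @return An integer seed.
#' @export
replicate_seed <- function(master_seed, scenario_index, replicate_index) {
  as.integer((as.double(master_seed) + 1000003 * scenario_index +
                7919 * replicate_index) %% 2147483647)
}

#' Per-patient life-year gains under common random numbers
#'
#' Draws one uniform survival quantile per patient and evaluates both
#' survival laws at that shared quantile. Identified driver-positive
#' patients gain the difference between their matched and unmatched
#' draws; everyone else gains zero. Sharing the quantile makes the gain
#' the within-patient counterfactual contrast, and the gain is floored at
#' zero: matched therapy is modelled as never inferior to the same
#' patient's unmatched counterfactual (the two calibrated curves cross
#' only past ~215 months, at survival below 2e-5).
#'
#' @param cohort Cohort with `detected` populated (see [detect()]).
#' @param matched_model,unmatched_model The two [weibull_survival()] laws.
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @param rmst_horizon_months Optional horizon; when set, both draws are
#'   truncated at it before differencing.
#' @return The cohort with numeric columns `ly_matched_months`,
#'   `ly_unmatched_months` and `lyg_months` appended.
#' @export
patient_lyg_months <- function(cohort, matched_model, unmatched_model,
                               seed = NULL, rmst_horizon_months = NULL) {
  stopifnot(is.data.frame(cohort),
            inherits(matched_model, "weibull_survival"),
            inherits(unmatched_model, "weibull_survival"))
  if (is.null(cohort$detected))
    stop("patient_lyg_months: cohort must have detection flags (run detect first)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  u <- stats::runif(n)
  t_matched <- quantile_months(matched_model, u)
  t_unmatched <- quantile_months(unmatched_model, u)
  if (!is.null(rmst_horizon_months)) {
    t_matched <- pmin(t_matched, rmst_horizon_months)
    t_unmatched <- pmin(t_unmatched, rmst_horizon_months)
  }
  identified <- cohort$detected & cohort$driver_gene != "NONE"
  gain <- numeric(n)
  gain[identified] <- pmax(0, t_matched[identified] - t_unmatched[identified])
  cohort$ly_matched_months <- t_matched
  cohort$ly_unmatched_months <- t_unmatched
  cohort$lyg_months <- gain
  cohort
}

#' Empirical 95% credible interval
#'
#' The 2.5th and 97.5th percentiles of the replicate distribution, using
#' inclusive linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param samples Numeric vector with at least one value.
#' @return Length-2 numeric vector `c(low, high)`.
#' @export
credible_interval <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("credible_interval: need at least one sample")
  if (anyNA(samples)) return(c(NA_real_, NA_real_))
  stats::quantile(samples, probs = c(0.025, 0.975), type = 7, names = FALSE)
}

# Single Monte Carlo replicate of one scenario; returns the per-replicate
# population-level metrics.
run_replicate <- function(config, seed) {
  set.seed(seed)
  cohort <- generate_cohort(config$cohort_size, config$prevalences)
  cohort <- allocate_tests(cohort, config$mix)
  cohort <- detect(cohort, config$panels, config$performance)
  cohort <- patient_lyg_months(cohort, config$matched_model,
                               config$unmatched_model,
                               rmst_horizon_months = config$rmst_horizon_months)
  identified <- cohort$detected & cohort$driver_gene != "NONE"
  n <- nrow(cohort)
  testing_cost <- testing_cost_realized(
    sum(cohort$assigned_test == "SGT"),
    sum(cohort$assigned_test == "NGS"), config$costs)
  treated_ly <- sum(cohort$ly_matched_months[identified]) / 12
  treatment_cost <- treatment_cost_total(treated_ly, config$costs)
  total_lyg <- sum(cohort$lyg_months) / 12
  total_cost <- testing_cost + treatment_cost
  c(identified_fraction = sum(identified) / n,
    total_lyg_years = total_lyg,
    testing_cost_usd = testing_cost,
    treatment_cost_usd = treatment_cost,
    total_cost_usd = total_cost,
    cost_per_lyg_usd = if (total_lyg > 0) total_cost / total_lyg else NA_real_)
}

#' Run one testing-mix scenario
#'
#' Runs `replicates` Monte Carlo cohorts (generate, allocate, detect,
#' accrue life-years and costs) and summarizes each outcome by its
#' replicate mean and 95% percentile credible interval. Fully
#' reproducible from the seed and configuration. In a scenario with no
#' testing the cost per life-year gained is undefined and reported as NA.
#'
#' @param config A [scenario_config()].
#' @param scenario_index Zero-based index used in the sub-seed lineage;
#'   [sweep_scenarios()] supplies it.
#' @return A one-row data.frame (the scenario summary).
#' @export
run_scenario <- function(config, scenario_index = 0L) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- vapply(seq_len(config$replicates), function(r) {
    run_replicate(config, replicate_seed(config$seed, scenario_index, r))
  }, numeric(6))
  summarize_metric <- function(name) {
    x <- reps[name, ]
    if (all(is.na(x))) return(c(NA_real_, NA_real_, NA_real_))
    ci <- credible_interval(x)
    c(mean(x), ci[1], ci[2])
  }
  m <- lapply(c("identified_fraction", "total_lyg_years", "testing_cost_usd",
                "treatment_cost_usd", "total_cost_usd", "cost_per_lyg_usd"),
              summarize_metric)
  names(m) <- c("identified_fraction", "total_lyg_years", "testing_cost_usd",
                "treatment_cost_usd", "total_cost_usd", "cost_per_lyg_usd")
  data.frame(
    untested_fraction = config$mix$untested,
    sgt_fraction = config$mix$sgt,
    ngs_fraction = config$mix$ngs,
    identified_fraction = m$identified_fraction[1],
    identified_fraction_lo = m$identified_fraction[2],
    identified_fraction_hi = m$identified_fraction[3],
    identified_fraction_se = stats::sd(reps["identified_fraction", ]) /
      sqrt(config$replicates),
    total_lyg_years = m$total_lyg_years[1],
    total_lyg_lo = m$total_lyg_years[2],
    total_lyg_hi = m$total_lyg_years[3],
    total_lyg_se = stats::sd(reps["total_lyg_years", ]) /
      sqrt(config$replicates),
    testing_cost_usd = m$testing_cost_usd[1],
    treatment_cost_usd = m$treatment_cost_usd[1],
    treatment_cost_lo = m$treatment_cost_usd[2],
    treatment_cost_hi = m$treatment_cost_usd[3],
    total_cost_usd = m$total_cost_usd[1],
    total_cost_lo = m$total_cost_usd[2],
    total_cost_hi = m$total_cost_usd[3],
    cost_per_lyg_usd = m$cost_per_lyg_usd[1],
    cost_per_lyg_lo = m$cost_per_lyg_usd[2],
    cost_per_lyg_hi = m$cost_per_lyg_usd[3],
    replicates = config$replicates,
    scenario_index = scenario_index
  )
}

#' Closed-form scenario expectation
#'
#' Exact expected values of the scenario outcomes, with no sampling: the
#' identified fraction comes from [identified_fraction_analytic()], the
#' expected total life-years gained is
#' N * q * (E\[matched\] - E\[unmatched\]) / 12, and the expected costs
#' come from the closed-form economics. Used as the point-estimate path
#' and as the oracle the Monte Carlo engine is tested against.
#'
#' @param config A [scenario_config()].
#' @return A one-row data.frame of point values (no intervals).
#' @export
analytic_expectation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  q <- identified_fraction_analytic(config$mix, config$prevalences,
                                    config$panels, config$performance)
  n <- config$cohort_size
  if (is.null(config$rmst_horizon_months)) {
    e_matched <- mean_months(config$matched_model)
    e_unmatched <- mean_months(config$unmatched_model)
  } else {
    e_matched <- rmst_months(config$matched_model, config$rmst_horizon_months)
    e_unmatched <- rmst_months(config$unmatched_model, config$rmst_horizon_months)
  }
  total_lyg <- n * q * (e_matched - e_unmatched) / 12
  testing_cost <- testing_cost_total(config$mix, n, config$costs)
  treatment_cost <- treatment_cost_total(n * q * e_matched / 12, config$costs)
  total_cost <- testing_cost + treatment_cost
  data.frame(
    untested_fraction = config$mix$untested,
    sgt_fraction = config$mix$sgt,
    ngs_fraction = config$mix$ngs,
    identified_fraction = q,
    total_lyg_years = total_lyg,
    testing_cost_usd = testing_cost,
    treatment_cost_usd = treatment_cost,
    total_cost_usd = total_cost,
    cost_per_lyg_usd = if (total_lyg > 0) total_cost / total_lyg else NA_real_
  )
}

#' Sweep the SGT/NGS testing grid
#'
#' Holds the untested share fixed and sweeps the NGS share of the tested
#' population from 0 to its maximum in steps of `step` (17 scenarios at
#' the default 5-percentage-point step with 20% untested), with the SGT
#' share taking the balance. Each grid point runs with its own
#' deterministically derived sub-seeds. Optionally appends the
#' full-testing scenario (nobody untested, all NGS).
#'
#' @param config A [scenario_config()]; its `mix` supplies the untested
#'   share, and its other fields apply to every grid point.
#' @param step Grid step as a fraction of the population (default 0.05).
#'   Must divide the tested share evenly.
#' @param include_full_testing Append the untested 0 / NGS 1.0 scenario?
#' @param analytic If TRUE return the closed-form expectations instead of
#'   Monte Carlo summaries (no intervals; fast).
#' @return A data.frame with one row per scenario, ordered by increasing
#'   NGS share.
#' @export
sweep_scenarios <- function(config, step = 0.05,
                            include_full_testing = FALSE,
                            analytic = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  tested <- 1 - config$mix$untested
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > tested)
    stop("step must be a fraction in (0, tested share]")
  n_steps <- tested / step
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("step must divide the tested share (", tested, ") evenly")
  ngs_grid <- seq(0, tested, by = step)
  # guard against accumulation error at the endpoint
  ngs_grid[length(ngs_grid)] <- tested
  configs <- lapply(ngs_grid, function(f) {
    cfg <- config
    cfg$mix <- testing_mix(config$mix$untested, tested - f, f)
    cfg
  })
  if (include_full_testing)
    configs <- c(configs, list({
      cfg <- config
      cfg$mix <- testing_mix(0, 0, 1)
      cfg
    }))
  rows <- lapply(seq_along(configs), function(i) {
    if (analytic) analytic_expectation(configs[[i]])
    else run_scenario(configs[[i]], scenario_index = i - 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Incremental life-years and cost per step of NGS uptake
#'
#' Successive differences of total life-years gained and of cost per
#' life-year gained along a sweep, rescaled to a 10-percentage-point
#' increase in the NGS share, plus their averages across the sweep.
#'
#' @param summaries Sweep output ([sweep_scenarios()]), at least 2 rows.
#' @param step_size NGS-share increment between successive rows.
#' @return A list with `per_step` (data.frame of rescaled increments) and
#'   `average` (named vector: mean LYG and mean cost-per-LYG change per
#'   10-point NGS increase).
#' @export
incremental_per_step <- function(summaries, step_size = 0.05) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2,
            is.numeric(step_size), step_size > 0)
  scale <- 0.10 / step_size
  d_lyg <- diff(summaries$total_lyg_years) * scale
  d_cpl <- diff(summaries$cost_per_lyg_usd) * scale
  per_step <- data.frame(
    ngs_fraction_from = utils::head(summaries$ngs_fraction, -1),
    ngs_fraction_to = utils::tail(summaries$ngs_fraction, -1),
    lyg_per_10pt = d_lyg,
    cost_per_lyg_change_per_10pt = d_cpl
  )
  list(per_step = per_step,
       average = c(lyg_per_10pt = mean(d_lyg),
                   cost_per_lyg_change_per_10pt = mean(d_cpl)))
}
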
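# Independent numerical oracles, deliberately separate from the package's
# closed-form paths.

# 2-D least-squares fit of (shape, scale) to the two survival anchors,
# optimized on the log scale from a neutral start.
oracle_fit_weibull <- function(median_months, horizon_months, survival_at_horizon) {
  obj <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2])
    s <- function(t) exp(-(t / lam)^k)
    (s(median_months) - 0.5)^2 + (s(horizon_months) - survival_at_horizon)^2
  }
  fit <- stats::optim(c(0, log(median_months)), obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 2000))
  list(shape = exp(fit$par[1]), scale_months = exp(fit$par[2]),
       objective = fit$value)
}

# Trapezoid quadrature of a survival curve, refined until converged.
oracle_trapezoid_auc <- function(survfun, upper, tol = 1e-9) {
  n <- 256L
  prev <- Inf
  repeat {
    t <- seq(0, upper, length.out = n + 1L)
    s <- survfun(t)
    val <- sum((s[-1] + s[-length(s)]) / 2) * (upper / n)
    if (abs(val - prev) < tol || n > 2^22) return(val)
    prev <- val
    n <- n * 2L
  }
}

matched_fit <- function() fit_weibull_anchors(survival_anchors(39, 60, 0.25))
unmatched_fit <- function() fit_weibull_anchors(survival_anchors(14, 60, 0.05))

# small-but-honest Monte Carlo config for engine tests
small_config <- function(n = 4000, replicates = 10L, seed = 42L, ...) {
  scenario_config(cohort_size = n, replicates = replicates, seed = seed, ...)
}
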
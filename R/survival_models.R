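#' Survival anchors for Weibull calibration
#'
#' Bundle a median survival time with one landmark survival probability
#' (e.g. 5-year survival). Two such quantile anchors pin down both
#' parameters of a Weibull survival law exactly.
#'
#' @param median_months Median overall survival, in months (> 0).
#' @param horizon_months Landmark time, in months (> 0, different from the
#'   median). The default 60 corresponds to 5-year survival.
#' @param survival_at_horizon Survival probability at `horizon_months`,
#'   strictly between 0 and 1. Must sit on the correct side of 0.5: below
#'   0.5 when the horizon is beyond the median, above 0.5 when it is
#'   before, else no Weibull passes through both anchors.
#'
#' @return An object of class `survival_anchors`.
#' @examples
#' survival_anchors(39, 60, 0.25)  # matched targeted therapy
#' survival_anchors(14, 60, 0.05)  # unmatched chemoimmunotherapy
#' @export
survival_anchors <- function(median_months, horizon_months = 60,
                             survival_at_horizon) {
  stopifnot(is.numeric(median_months), length(median_months) == 1L,
            is.numeric(horizon_months), length(horizon_months) == 1L,
            is.numeric(survival_at_horizon), length(survival_at_horizon) == 1L)
  if (!is.finite(median_months) || median_months <= 0)
    stop("invalid anchors: median_months must be a positive finite time")
  if (!is.finite(horizon_months) || horizon_months <= 0)
    stop("invalid anchors: horizon_months must be a positive finite time")
  if (survival_at_horizon <= 0 || survival_at_horizon >= 1)
    stop("invalid anchors: survival_at_horizon must lie strictly in (0, 1)")
  if (horizon_months == median_months)
    stop("invalid anchors: horizon_months must differ from median_months")
  if (horizon_months > median_months && survival_at_horizon >= 0.5)
    stop("invalid anchors: survival beyond the median must be < 0.5 ",
         "(no monotone Weibull law passes through both anchors)")
  if (horizon_months < median_months && survival_at_horizon <= 0.5)
    stop("invalid anchors: survival before the median must be > 0.5 ",
         "(no monotone Weibull law passes through both anchors)")
  structure(
    list(median_months = median_months,
         horizon_months = horizon_months,
         survival_at_horizon = survival_at_horizon),
    class = "survival_anchors"
  )
}

#' Weibull survival law
#'
#' Survival function S(t) = exp(-(t / scale)^shape), time in months.
#'
#' @param shape Dimensionless shape parameter k > 0.
#' @param scale_months Scale parameter lambda > 0, in months.
#' @return An object of class `weibull_survival`.
#' @export
weibull_survival <- function(shape, scale_months) {
  stopifnot(is.numeric(shape), length(shape) == 1L,
            is.numeric(scale_months), length(scale_months) == 1L)
  if (!is.finite(shape) || shape <= 0)
    stop("invalid Weibull model: shape must be a positive finite number")
  if (!is.finite(scale_months) || scale_months <= 0)
    stop("invalid Weibull model: scale_months must be a positive finite time")
  structure(list(shape = shape, scale_months = scale_months),
            class = "weibull_survival")
}

#' @export
print.weibull_survival <- function(x, ...) {
  cat(sprintf(
    "Weibull survival law: shape = %.6g, scale = %.6g months (median %.4g months)\n",
    x$shape, x$scale_months, x$scale_months * log(2)^(1 / x$shape)))
  invisible(x)
}

#' Calibrate a Weibull survival law to median and landmark anchors
#'
#' Solves S(m) = 0.5 and S(h) = S_h in closed form:
#' shape k = log(log(S_h) / log(0.5)) / log(h / m) and
#' scale lambda = m / log(2)^(1/k). Two anchors determine the two
#' parameters exactly; no iterative fitting is involved.
#'
#' @param anchors A [survival_anchors()] object.
#' @return A [weibull_survival()] model reproducing both anchors to well
#'   under 1e-9 in survival probability.
#' @examples
#' fit_weibull_anchors(survival_anchors(39, 60, 0.25))
#' @export
fit_weibull_anchors <- function(anchors) {
  stopifnot(inherits(anchors, "survival_anchors"))
  m <- anchors$median_months
  h <- anchors$horizon_months
  sh <- anchors$survival_at_horizon
  k <- log(log(sh) / log(0.5)) / log(h / m)
  if (!is.finite(k) || k <= 0)
    stop("anchor calibration failed: implied shape is not positive ",
         "(anchors do not define a monotone Weibull survival curve)")
  lambda <- m / log(2)^(1 / k)
  weibull_survival(shape = k, scale_months = lambda)
}

#' Evaluate a Weibull survival curve
#'
#' @param model A [weibull_survival()] model.
#' @param t Vector of times in months, each >= 0.
#' @return S(t) = exp(-(t / scale)^shape), vectorised over `t`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "weibull_survival"), is.numeric(t))
  if (any(t < 0)) stop("survival_at: negative times are not allowed")
  stats::pweibull(t, shape = model$shape, scale = model$scale_months,
                  lower.tail = FALSE)
}

#' Mean survival time of a Weibull law
#'
#' @param model A [weibull_survival()] model.
#' @return lambda * Gamma(1 + 1/k), in months.
#' @export
mean_months <- function(model) {
  stopifnot(inherits(model, "weibull_survival"))
  model$scale_months * gamma(1 + 1 / model$shape)
}

#' Restricted mean survival time
#'
#' Integrates S(t) from 0 to `horizon` by adaptive quadrature.
#'
#' @param model A [weibull_survival()] model.
#' @param horizon Truncation horizon in months (> 0).
#' @return RMST in months; never exceeds `min(horizon, mean_months(model))`.
#' @export
rmst_months <- function(model, horizon) {
  stopifnot(inherits(model, "weibull_survival"),
            is.numeric(horizon), length(horizon) == 1L)
  if (!is.finite(horizon) || horizon <= 0)
    stop("rmst_months: horizon must be a positive finite time")
  stats::integrate(function(t) survival_at(model, t),
                   lower = 0, upper = horizon,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Draw survival times by inverse transform
#'
#' Each draw is t = lambda * (-log U)^(1/k) with U uniform on (0, 1), the
#' inverse of the survival function. A given seed yields the same sequence.
#'
#' @param model A [weibull_survival()] model.
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used inside the scenario engine, which seeds per replicate).
#' @return Numeric vector of `n` survival times in months.
#' @export
sample_months <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "weibull_survival"),
            is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  model$scale_months * (-log(stats::runif(n)))^(1 / model$shape)
}

#' Survival-quantile time
#'
#' Time at which the survival curve reaches probability `u`; the shared-
#' quantile device behind common-random-number life-year gains.
#'
#' @param model A [weibull_survival()] model.
#' @param u Vector of survival probabilities in (0, 1].
#' @return Times t with S(t) = u, in months.
#' @export
quantile_months <- function(model, u) {
  stopifnot(inherits(model, "weibull_survival"), is.numeric(u))
  if (any(u <= 0 | u > 1))
    stop("quantile_months: survival probabilities must lie in (0, 1]")
  stats::qweibull(u, shape = model$shape, scale = model$scale_months,
                  lower.tail = FALSE)
}

#' Rescale a Weibull law to a target mean
#'
#' Keeps the shape and adjusts the scale so the distribution mean equals
#' `target_mean_months`. Used for sensitivity analysis when an external
#' estimate of mean survival should replace the anchor-implied mean.
#'
#' @param model A [weibull_survival()] model.
#' @param target_mean_months Desired mean survival in months (> 0).
#' @return A new [weibull_survival()] model.
#' @export
override_mean <- function(model, target_mean_months) {
  stopifnot(inherits(model, "weibull_survival"),
            is.numeric(target_mean_months), length(target_mean_months) == 1L)
  if (!is.finite(target_mean_months) || target_mean_months <= 0)
    stop("override_mean: target mean must be a positive finite time")
  weibull_survival(shape = model$shape,
                   scale_months = target_mean_months / gamma(1 + 1 / model$shape))
}
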
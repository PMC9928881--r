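#' Cost inputs
#'
#' Per-test reimbursement figures and the annual treatment cost, in USD.
#' Defaults are CMS reimbursement for single-gene testing ($723.30 per
#' test) and NGS panel testing ($627.50 per test), and a generalized
#' $10,000 per treatment-year averaged over targeted therapy and
#' chemoimmunotherapy.
#'
#' @param sgt_usd Cost per SGT test.
#' @param ngs_usd Cost per NGS test.
#' @param treatment_usd_per_year Treatment cost per life-year on therapy.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(sgt_usd = 723.30, ngs_usd = 627.50,
                        treatment_usd_per_year = 10000) {
  c_ <- c(sgt_usd = sgt_usd, ngs_usd = ngs_usd,
          treatment_usd_per_year = treatment_usd_per_year)
  if (!is.numeric(c_) || any(!is.finite(c_)) || any(c_ < 0))
    stop("all cost inputs must be non-negative finite amounts")
  structure(as.list(c_), class = "cost_inputs")
}

#' Expected total testing cost
#'
#' Analytic path: n * (sgt_fraction * c_SGT + ngs_fraction * c_NGS). The
#' Monte Carlo engine instead prices realized assignment counts via
#' [testing_cost_realized()].
#'
#' @param mix A [testing_mix()].
#' @param n Population size.
#' @param costs A [cost_inputs()].
#' @return Total testing cost in USD.
#' @export
testing_cost_total <- function(mix, n, costs = cost_inputs()) {
  stopifnot(inherits(mix, "testing_mix"), inherits(costs, "cost_inputs"),
            is.numeric(n), length(n) == 1L, n >= 0)
  n * (mix$sgt * costs$sgt_usd + mix$ngs * costs$ngs_usd)
}

#' Realized testing cost from assignment counts
#'
#' @param n_sgt,n_ngs Numbers of patients actually assigned to each test.
#' @param costs A [cost_inputs()].
#' @return Total testing cost in USD.
#' @export
testing_cost_realized <- function(n_sgt, n_ngs, costs = cost_inputs()) {
  stopifnot(inherits(costs, "cost_inputs"), n_sgt >= 0, n_ngs >= 0)
  n_sgt * costs$sgt_usd + n_ngs * costs$ngs_usd
}

#' Total treatment cost over treated life-years
#'
#' Treatment cost accrues for identified driver-positive patients over
#' their full matched-therapy survival duration.
#'
#' @param treated_life_years Total life-years on therapy (>= 0).
#' @param costs A [cost_inputs()].
#' @return Total treatment cost in USD.
#' @export
treatment_cost_total <- function(treated_life_years, costs = cost_inputs()) {
  stopifnot(inherits(costs, "cost_inputs"),
            is.numeric(treated_life_years), length(treated_life_years) == 1L)
  if (!is.finite(treated_life_years) || treated_life_years < 0)
    stop("treated_life_years must be non-negative")
  treated_life_years * costs$treatment_usd_per_year
}

#' Cost per life-year gained
#'
#' @param total_cost Total scenario cost in USD.
#' @param total_lyg Total life-years gained (> 0).
#' @return USD per life-year gained.
#' @export
cost_per_lyg <- function(total_cost, total_lyg) {
  stopifnot(is.numeric(total_cost), is.numeric(total_lyg),
            length(total_cost) == 1L, length(total_lyg) == 1L)
  if (!is.finite(total_lyg) || total_lyg <= 0)
    stop("cost per LYG is undefined when total life-years gained is not positive")
  total_cost / total_lyg
}
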
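---
title: "A population microsimulation of biomarker testing strategies in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population microsimulation of biomarker testing strategies in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotestsim)
```

## The question the model answers

Roughly 29.3% of patients with newly diagnosed advanced nonsquamous
non-small-cell lung cancer carry one of seven actionable driver oncogenes
(ADOs) — EGFR, ALK, ROS1, BRAF, RET, MET or NTRK — for which an approved
matched targeted therapy exists. Whether a given patient's driver is found
depends on which test they receive: conventional single-gene testing (SGT)
assays only EGFR and ALK (a combined 19% of the population), while a
multigene next-generation sequencing (NGS) panel covers all seven. An
unidentified carrier receives standard chemoimmunotherapy and forgoes the
survival benefit of matched therapy.

`oncotestsim` simulates a national annual incidence cohort of 89,000
patients, partitions it into untested / SGT-tested / NGS-tested fractions,
determines which drivers are identified, and converts the identification
gap into population totals of life-years gained (LYG) and cost per
life-year gained as NGS replaces SGT. The untested share is held at 20%
throughout; the NGS share of the population sweeps from 0% to 80% in
5-point steps, with SGT taking the balance.

## Survival model

Survival under each treatment condition follows a Weibull law
$S(t) = \exp\{-(t/\lambda)^k\}$ with time in months. Each law is pinned
down exactly by two quantile anchors — the median $m$ and a landmark
survival probability $S_h$ at horizon $h$ — through the closed form

$$k = \frac{\log\left(\log S_h / \log 0.5\right)}{\log(h/m)}, \qquad
\lambda = \frac{m}{(\log 2)^{1/k}}.$$

The defaults are literature-consensus aggregates for the two arms:

| arm | median | 5-year survival | fitted shape | fitted scale | mean |
|---|---|---|---|---|---|
| matched targeted therapy | 39 mo | 25% | 1.609 | 48.98 mo | 43.89 mo |
| unmatched chemoimmunotherapy | 14 mo | 5% | 1.006 | 20.16 mo | 20.11 mo |

Because two anchors determine the two parameters exactly, no iterative
fitting is involved; an independent two-dimensional optimizer is retained
in the test suite purely as a cross-check. Anchors must sit on the correct
side of 0.5 relative to the median (landmark survival below 0.5 beyond the
median, above 0.5 before it); anything else is rejected with a diagnostic
naming the violated constraint, since no monotone Weibull curve passes
through such a pair.

Times are kept in months internally because the anchors are stated in
months; all reported life-years divide by 12 at the end. Survival is
unbounded by default — no administrative censoring horizon is imposed. An
optional restricted-mean horizon (`rmst_horizon_months`) truncates both
draws when a bounded analysis is wanted.

## Cohort synthesis: what the generator emulates

The generator draws one categorical outcome per patient over the seven
driver genes and the driver-negative remainder, so drivers are mutually
exclusive — co-occurring drivers are rare in practice, and the design
arithmetic (19% + 10.3% = 29.3%) presumes disjoint groups. Only the two
group sums are treated as ground truth; the per-gene split within them is
configurable, with defaults (EGFR 15.0%, ALK 4.0%, ROS1 2.6%, BRAF 2.2%,
MET 3.0%, RET 2.0%, NTRK 0.5%) chosen to reflect the relative literature
frequencies while hitting the 19% / 29.3% sums exactly. A regression test
verifies that reallocating mass among the five NGS-only genes changes no
scenario output: at group-level panels and survival laws, only the sums
matter. KRAS is excluded from the panel because its matched therapy was
second-line at the horizon the inputs describe.

The generator deliberately omits features of real populations that the
group-level model cannot use: patient covariates (age, sex, histology),
tissue availability and turnaround time, test-eligibility confounding with
biology, and per-gene survival heterogeneity. Passing tests therefore
demonstrate internal consistency of the model at its stated inputs, not
calibration against any real registry.

## Testing, detection and the identification identity

Test assignment is an independent categorical draw with the mix
probabilities — eligibility is assumed unrelated to tumour biology, which
is what makes the identification arithmetic exact. Sensitivity and
specificity default to 100%; at those defaults a driver is detected if and
only if it is on the assigned panel. (Imperfect assays are supported as an
extension: detection then thins by sensitivity, and false-positive calls
in driver-negative tested patients arise at rate 1 − specificity with a
uniformly random in-panel label.)

The exact identified fraction is
$q = \sum_g p_g \,[\,f_{SGT}\,\mathbf{1}(g \in SGT) +
f_{NGS}\,\mathbf{1}(g \in NGS)\,]\times\text{sens}$,
which at the defaults gives the three bookkeeping facts the model is built
around: SGT-only testing identifies 15.2% of the population, full NGS
replacement identifies 23.44% (reported as 23.4%), and the shortfall
decomposes into 3.8% EGFR/ALK carriers missed purely through the untested
20% plus 10.3% of the population carrying drivers a two-gene assay can
never see.

## Life-years gained and the common-random-number device

Per-patient benefit is a within-patient counterfactual contrast: one
uniform quantile $U$ is drawn per patient and both survival laws are
inverted at it, so an identified driver-positive patient gains
$t_{\text{matched}}(U) - t_{\text{unmatched}}(U)$ months. Unidentified
carriers and driver-negative patients gain zero. Sharing the quantile
removes between-arm sampling noise from the per-patient gain and makes the
gain non-negative wherever the matched curve dominates.

One numerical subtlety: the two calibrated curves cross in the extreme
tail (near $t \approx 215$ months, where survival is below $2\times
10^{-5}$), because the unmatched shape is slightly above 1 while the
matched shape is 1.6. About two patients per 100,000 would therefore draw
a formally negative gain. The model floors the gain at zero — matched
therapy is treated as never inferior to the same patient's unmatched
counterfactual — which introduces a bias below $10^{-3}$ months per
identified patient, orders of magnitude under Monte Carlo error. The
closed-form expectation deliberately ignores the floor and uses the
difference of means (23.78 months, i.e. 1.98 life-years per identified
patient).

At the median quantile the gain is 39 − 14 = 25 months; in expectation it
is the difference of the two Weibull means. Expected total LYG in a
scenario is then $N \, q \, (\mu_m - \mu_u)/12$ — the analytic path the
Monte Carlo engine is tested against at every grid point.

## Costs

Testing costs use CMS reimbursement rates: \$723.30 per SGT-tested
patient and \$627.50 per NGS-tested patient (the panel is cheaper than
the two single-gene assays it replaces). Treatment cost is a generalized
\$10,000 per treatment-year. It accrues for identified driver-positive
patients over their full matched-therapy survival; chemoimmunotherapy for
everyone else is treated as common background spending and excluded, so
scenarios differ only through testing spend and matched-treatment spend.
This accrual rule is the design choice that makes the cost side of the
model internally consistent with LYG accruing only to identified
patients. No discounting is applied to costs or life-years. Cost per LYG
is total cost (testing + treatment) over total LYG, and is reported as
undefined — not infinite — in a no-testing scenario.

## Monte Carlo engine, intervals and reproducibility

Each scenario runs `replicates` independent cohorts (default 200; the
credible-interval width is reported so users can judge whether to raise
it). Every outcome is summarized by its replicate mean and a 95% credible
interval from the 2.5th and 97.5th percentiles of the replicate
distribution, computed with inclusive linear interpolation between order
statistics (`quantile()` type 7). Replicate-level, not patient-level,
resampling defines the intervals.

Sub-seeds follow a documented lineage,
`(master + 1000003 * scenario_index + 7919 * replicate_index) mod (2^31 - 1)`,
so any scenario or replicate can be reproduced in isolation; rerunning a
sweep with the same configuration and master seed reproduces
`results.csv` byte for byte (numbers are serialized at 17 significant
digits, so read-back equals the in-memory value exactly). The run
manifest echoes the full configuration, package version, master seed and
per-scenario sub-seeds.

## Design choices that were genuinely open

* **Aggregate versus per-gene survival laws.** The model fits one
  aggregate matched law and one aggregate unmatched law. Published
  population totals built from per-gene trial curves can imply a larger
  per-identified-patient gain (≈ 2.9 life-years) than any single Weibull
  through the aggregate anchors can produce (1.98); since per-gene anchors
  are not part of the model's inputs, the package keeps the aggregate
  parameterization and instead exposes
  `survival: matched_mean_override_months` (and `override_mean()`), which
  rescales the matched law to an externally supplied mean while keeping
  its shape, for sensitivity analysis against such estimates.
* **Identified-only accrual.** Both LYG and treatment cost accrue only to
  identified driver-positive patients. This makes total LYG exactly
  proportional to the identified count across scenarios — the property
  that lets the analytic path serve as an oracle for the engine.
* **Analysis-workflow shape.** The numbered scripts under `analysis/` are
  the intended interface (calibrate, identification table, sweep,
  figures); the package functions underneath are what the tests and the
  acceptance script exercise. No separate command-line binary is
  provided.

## Numerical and testing notes

RMST uses adaptive quadrature at a relative tolerance of 1e−10 and is
cross-checked against trapezoid refinement; anchor round-trips are
verified to 1e−9 in survival probability; sampling is plain inverse
transform. The engine's statistical tests run at reduced problem sizes
chosen to keep the suite brisk while leaving Monte Carlo tolerances
honest (3 standard errors throughout): the oracle-equivalence sweep uses
the full 89,000-patient cohort with 100 replicates, the determinism check
uses 8,000 patients with 20 replicates, and distributional checks use
10^5–10^6 draws. The full default sweep (89,000 × 200 × 17) runs in
about a minute and a half on one CPU via `analysis/03_sweep.R`.

## Limitations

Only first-line treatment is modelled — no later lines, no sequential or
reflex testing, no rebiopsy or tissue-exhaustion logic, no liquid-biopsy
pathway. Outcomes are life-years, not quality-adjusted life-years, and no
discounting is applied. Costs cover testing and an averaged treatment
price only. The credible intervals quantify simulation noise at fixed
inputs, not parameter uncertainty in the prevalences, anchors or costs.
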
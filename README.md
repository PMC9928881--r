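# oncotestsim

A population-level microsimulation of biomarker testing strategies in
advanced nonsquamous non-small-cell lung cancer (NSCLC). The model asks
what the United States annual incidence cohort (89,000 patients) stands
to gain — in life-years and in cost per life-year gained (LYG) — as
multigene next-generation sequencing (NGS) panels replace single-gene
testing (SGT) for actionable driver oncogenes (ADOs).

Seven drivers with approved matched therapies are modelled (EGFR, ALK,
ROS1, BRAF, RET, MET, NTRK; 29.3% of patients combined). SGT assays only
EGFR and ALK (19% combined), so every other carrier is invisible to it.
20% of patients receive no testing; the NGS share of the population
sweeps from 0% to 80% in 5-point steps, with SGT taking the balance.

## Model core

* Survival under each arm is Weibull, `S(t) = exp(-(t/λ)^k)`, calibrated
  in closed form to two anchors (median m, landmark survival S_h at
  horizon h):

  ```
  k = log(log S_h / log 0.5) / log(h/m),   λ = m / (log 2)^(1/k)
  ```

  Matched targeted therapy: median 39 months, 5-year survival 25%
  (k = 1.609, λ = 48.98 mo). Unmatched chemoimmunotherapy: median 14
  months, 5-year survival 5% (k = 1.006, λ = 20.16 mo).
* Each patient draws one driver status (categorical over the prevalence
  table), one test assignment (categorical over the mix), and one shared
  survival quantile; an identified carrier gains the difference between
  the matched and unmatched draws at that quantile, everyone else gains
  zero.
* Costs: $723.30 per SGT test, $627.50 per NGS test (CMS reimbursement),
  $10,000 per treatment-year accruing over identified patients'
  matched-therapy survival. Cost per LYG = total cost / total LYG.
* Outcomes are replicate means with 95% credible intervals from the
  2.5th/97.5th percentiles across Monte Carlo replicates (default 200),
  with exact closed-form expectations computed alongside as a
  cross-check.

See `vignettes/testing-strategy-microsimulation.Rmd` for the full
account of the model, its assumptions and design choices.

## Worked example

```r
library(oncotestsim)

# identification is exact arithmetic, no simulation needed
identified_fraction_analytic(testing_mix(0.20, 0.80, 0.00))  # SGT only
#> [1] 0.152
identified_fraction_analytic(testing_mix(0.20, 0.00, 0.80))  # NGS only
#> [1] 0.2344

# one Monte Carlo scenario at the study defaults
cfg <- load_config()                      # 89,000 patients, 200 replicates
cfg$mix <- testing_mix(0.20, 0.80, 0.00)
run_scenario(cfg)[, c("identified_fraction", "total_lyg_years",
                      "cost_per_lyg_usd")]
#>   identified_fraction total_lyg_years cost_per_lyg_usd
#> 1           0.1520703        26819.59         20371.13
```

So with SGT-only testing, 15.2% of the population has its driver
identified (of the 19% carrying EGFR/ALK alterations; 3.8% are missed
purely because they fall in the untested fifth, and a further 10.3%
carry drivers SGT cannot see), yielding ~26,800 life-years gained at
~$20,400 per life-year.

The analysis workflow lives in numbered scripts:

```sh
Rscript analysis/01_calibrate_survival.R   # fitted Weibull laws and means
Rscript analysis/02_identification.R       # exact identification table
Rscript analysis/03_sweep.R --seed 1       # 17-scenario Monte Carlo sweep
Rscript analysis/04_figures.R              # figures from the sweep
```

`analysis/03_sweep.R` prints one line per scenario and writes
`results/sweep/` (results.csv/json, manifest with full seed lineage,
analytic expectations, per-step increments). At the defaults it reports,
e.g.:

```
NGS    0%: identified 15.21%, LYG    26820 (95% CI    26378-   27260), cost/LYG $  20371
NGS   80%: identified 23.44%, LYG    41342 (95% CI    40866-   41878), cost/LYG $  19531
Each 10-point increase in NGS share adds on average 1815.3 LYG and changes cost per LYG by $-105.05.
```

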
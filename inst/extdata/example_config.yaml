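# Example configuration for oncotestsim::load_config().
# Every field is optional; omitted fields take the study defaults shown
# here. Survival laws may alternatively be given as fitted parameters
# ({shape, scale_months}) instead of anchors.
cohort_size: 89000
prevalences:
  EGFR: 0.150
  ALK: 0.040
  ROS1: 0.026
  BRAF: 0.022
  MET: 0.030
  RET: 0.020
  NTRK: 0.005
group_totals:          # validated sums of the table above
  sgt: 0.19            # EGFR + ALK (detectable by single-gene testing)
  panel: 0.293         # all seven genes (detectable by NGS)
mix:                   # population partition; must sum to 1
  untested: 0.20
  sgt: 0.65
  ngs: 0.15
survival:
  matched:             # identified carriers on matched targeted therapy
    median_months: 39
    horizon_months: 60
    survival_at_horizon: 0.25
  unmatched:           # standard chemoimmunotherapy
    median_months: 14
    horizon_months: 60
    survival_at_horizon: 0.05
  matched_mean_override_months: null   # sensitivity analysis: rescale the
                                       # matched law to this mean (months)
costs:
  sgt_usd: 723.30
  ngs_usd: 627.50
  treatment_usd_per_year: 10000
performance:
  sensitivity: 1.0
  specificity: 1.0
replicates: 200
seed: 1
rmst_horizon_months: null   # optional truncation horizon for life-years
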
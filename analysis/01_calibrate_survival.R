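#!/usr/bin/env Rscript
# Calibrate the two Weibull survival laws from their median / 5-year
# anchors and record the fitted parameters and implied means.
#
# Matched targeted therapy:     median 39 months, 5-year survival 25%
# Unmatched chemoimmunotherapy: median 14 months, 5-year survival 5%

suppressPackageStartupMessages(library(oncotestsim))

dir.create("results", showWarnings = FALSE)

laws <- list(
  matched = fit_weibull_anchors(survival_anchors(39, 60, 0.25)),
  unmatched = fit_weibull_anchors(survival_anchors(14, 60, 0.05))
)

tab <- do.call(rbind, lapply(names(laws), function(nm) {
  m <- laws[[nm]]
  data.frame(
    therapy = nm,
    shape = m$shape,
    scale_months = m$scale_months,
    median_months = m$scale_months * log(2)^(1 / m$shape),
    mean_months = mean_months(m),
    mean_years = mean_months(m) / 12,
    survival_5yr = survival_at(m, 60),
    rmst_60_months = rmst_months(m, 60)
  )
}))

write.csv(tab, "results/survival_parameters.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 5)

gap <- tab$mean_months[1] - tab$mean_months[2]
cat(sprintf(
  "\nExpected survival benefit of matched therapy: %.2f months (%.3f life-years) per identified patient\n",
  gap, gap / 12))
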
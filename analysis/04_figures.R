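#!/usr/bin/env Rscript
# Figures from the sweep written by analysis/03_sweep.R: identification
# and total life-years gained against the NGS share, with the
# current-practice mix (15% NGS / 65% SGT) marked.

suppressPackageStartupMessages({
  library(oncotestsim)
  library(ggplot2)
})

sweep_csv <- "results/sweep/results.csv"
if (!file.exists(sweep_csv))
  stop("run analysis/03_sweep.R first (missing ", sweep_csv, ")")
sw <- read.csv(sweep_csv)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

current_ngs <- 0.15

p1 <- ggplot(sw, aes(ngs_fraction, 100 * identified_fraction)) +
  geom_line(linewidth = 0.8, colour = "#2c7fb8") +
  geom_point(size = 1.6, colour = "#2c7fb8") +
  geom_vline(xintercept = current_ngs, linetype = "dashed", colour = "red") +
  scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
  labs(x = "NGS share of the population",
       y = "Patients with an identified driver (% of population)",
       title = "Driver identification as NGS replaces single-gene testing") +
  theme_minimal(base_size = 11)
ggsave("results/figures/identified_fraction.pdf", p1, width = 6, height = 4)

p2 <- ggplot(sw, aes(ngs_fraction, total_lyg_years)) +
  geom_ribbon(aes(ymin = total_lyg_lo, ymax = total_lyg_hi),
              fill = "#a6bddb", alpha = 0.6) +
  geom_line(linewidth = 0.8, colour = "#045a8d") +
  geom_vline(xintercept = current_ngs, linetype = "dashed", colour = "red") +
  scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
  labs(x = "NGS share of the population",
       y = "Total life-years gained (95% CI)",
       title = "Population life-years gained by testing mix") +
  theme_minimal(base_size = 11)
ggsave("results/figures/total_lyg.pdf", p2, width = 6, height = 4)

p3 <- ggplot(sw, aes(ngs_fraction, cost_per_lyg_usd)) +
  geom_ribbon(aes(ymin = cost_per_lyg_lo, ymax = cost_per_lyg_hi),
              fill = "#fdd49e", alpha = 0.6) +
  geom_line(linewidth = 0.8, colour = "#d95f0e") +
  geom_vline(xintercept = current_ngs, linetype = "dashed", colour = "red") +
  scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
  scale_y_continuous(labels = function(y) sprintf("$%s", format(y, big.mark = ","))) +
  labs(x = "NGS share of the population",
       y = "Cost per life-year gained (95% CI)",
       title = "Cost per life-year gained by testing mix") +
  theme_minimal(base_size = 11)
ggsave("results/figures/cost_per_lyg.pdf", p3, width = 6, height = 4)

message("wrote results/figures/{identified_fraction,total_lyg,cost_per_lyg}.pdf")
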
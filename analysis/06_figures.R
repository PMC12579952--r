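#!/usr/bin/env Rscript
# Figures from the tables written by the earlier steps: mean binned GRN
# responses per stimulus and location, and the learning curves with
# test-phase success per conditioning group.

suppressPackageStartupMessages({
  library(beetaste)
  library(ggplot2)
})

dir.create("results", showWarnings = FALSE)

bins <- read.csv("results/bins.csv")
bins$time_s <- 0.05 + (bins$time_bin - 1) * 0.1 + 0.1
prof <- aggregate(count ~ stimulus + location + time_bin + time_s, bins,
                  mean)
p1 <- ggplot(prof, aes(time_s, count * 10, colour = stimulus)) +
  geom_line() +
  facet_wrap(~location) +
  labs(x = "time after stimulus onset (s)", y = "firing rate (spikes/s)",
       title = "Mean binned GRN responses (simulated cohort)") +
  theme_bw()
ggsave("results/fig_grn_temporal.pdf", p1, width = 8, height = 3.5)

summ <- read.csv("results/conditioning_summaries.csv")
summ$panel <- sub("\\..*$", "", summ$bee_id)
long <- do.call(rbind, lapply(seq(10, 70, by = 10), function(k) {
  data.frame(panel = summ$panel, group = summ$group, visits = k,
             success = summ[[sprintf("s%d", k)]])
}))
curve <- aggregate(success ~ panel + group + visits, long, mean)
grp <- ifelse(curve$group == "control", "control",
              ifelse(grepl("positive", curve$group), "tastant-positive",
                     "tastant-negative"))
curve$role <- grp
p2 <- ggplot(curve, aes(visits, success, colour = role, linetype = role)) +
  geom_line() + geom_point(size = 1) +
  facet_wrap(~panel) +
  geom_hline(yintercept = 0.5, linetype = "dotted") +
  coord_cartesian(ylim = c(0.3, 1)) +
  labs(x = "training visits", y = "mean success rate (previous 10 visits)",
       title = "Learning curves per conditioning panel (simulated)") +
  theme_bw()
ggsave("results/fig_learning_curves.pdf", p2, width = 8, height = 6)

cat("Wrote results/fig_grn_temporal.pdf and results/fig_learning_curves.pdf\n")
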
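#!/usr/bin/env Rscript
# Condition-level statistics: unpaired Student's t-tests (fed vs starved)
# on peak offsets, the membrane-to-NSC ratio and normalized neuronal
# volume, with mean +/- SEM bar and five-number whisker plots.

source("analysis/00_common.R")

metrics <- read.csv(file.path(RESULTS_DIR, "metrics.csv"))
out <- file.path(RESULTS_DIR, "compare")

for (metric in c("nsc_offset", "neuron_offset", "membrane_nsc_ratio",
                 "neuron_volume_norm")) {
  cmp <- run_compare(metrics, metric, "fed", "starved", out_dir = out,
                     write_plots = TRUE)
  cat(sprintf("%-20s fed %.3g +/- %.2g vs starved %.3g +/- %.2g (mean +/- SEM): t=%.2f, p=%.2g %s\n",
              metric,
              cmp$summaries[[1]]$mean, cmp$summaries[[1]]$sem,
              cmp$summaries[[2]]$mean, cmp$summaries[[2]]$sem,
              cmp$t, cmp$p_value, cmp$stars))
}
cat(sprintf("Reports and plots in %s.\n", out))
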
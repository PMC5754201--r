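#!/usr/bin/env Rscript
# Morphometrics per specimen: supra-threshold membrane intensity, NSC
# count, membrane-to-NSC ratio and thresholded neuronal volume, plus the
# control-centred normalized volume.

source("analysis/00_common.R")

stacks <- load_cohort_stacks()
metrics <- do.call(rbind, lapply(stacks, function(s)
  niche_metrics(s, policies = POLICIES, min_volume = MIN_NUCLEUS_VOLUME)))

# centre neuronal volumes on the fed (control) mean
metrics$neuron_volume_norm <- normalize_volumes(
  metrics$neuron_volume,
  metrics$neuron_volume[metrics$condition == "fed"])

# merge in the peak offsets from the profiling stage
prof_file <- file.path(RESULTS_DIR, "profile", "profile_summary.csv")
if (file.exists(prof_file)) {
  prof <- read.csv(prof_file)
  metrics <- merge(metrics, prof[, c("specimen_id", "nsc_offset",
                                     "neuron_offset")],
                   by = "specimen_id", sort = TRUE)
}

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
write.csv(metrics, file.path(RESULTS_DIR, "metrics.csv"), row.names = FALSE)

cat(sprintf("Measured %d specimens; tidy table in %s/metrics.csv.\n",
            nrow(metrics), RESULTS_DIR))
for (cc in unique(metrics$condition)) {
  m <- metrics[metrics$condition == cc, ]
  cat(sprintf("%-8s membrane/NSC ratio %.0f +/- %.0f, NSC count %.1f, normalized neuron volume %.2f (n=%d).\n",
              cc, mean(m$membrane_nsc_ratio), sd(m$membrane_nsc_ratio),
              mean(m$nsc_count), mean(m$neuron_volume_norm), nrow(m)))
}
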
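# Shared settings for the analysis drivers: study conditions, thresholds,
# seeds and paths. Sourced by the numbered scripts; all computation lives
# in the nichechart package.

library(nichechart)

N_PER_ARM <- 6            # specimens (VNC-like scenes) per condition
SHAPE <- c(30, 128, 128)  # slices x height x width
FED_SEED <- 101
STARVED_SEED <- 201

STACK_DIR <- "scratch/stacks"
RESULTS_DIR <- "results"

# one threshold per channel, chosen once and held fixed across conditions
POLICIES <- list(glia = threshold_policy("glia", "absolute", 40),
                 nsc = threshold_policy("nsc", "absolute", 90),
                 neuron = threshold_policy("neuron", "absolute", 90))
MIN_NUCLEUS_VOLUME <- 10  # voxels

# Deterministic cohort loader: reads the TIFFs written by 01_simulate.R
# when present, otherwise regenerates the identical scenes from the seeds.
load_cohort_stacks <- function() {
  files <- sort(list.files(STACK_DIR, pattern = "\\.tif$", full.names = TRUE))
  if (length(files) == 2 * N_PER_ARM) {
    lapply(files, read_stack)
  } else {
    scenes <- c(simulate_cohort(N_PER_ARM, "fed", SHAPE, FED_SEED),
                simulate_cohort(N_PER_ARM, "starved", SHAPE, STARVED_SEED))
    lapply(scenes, `[[`, "stack")
  }
}
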
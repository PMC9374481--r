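# Shared setup for the analysis scripts: configuration, paths, and a cache
# so each numbered stage can be rerun from the previous stage's output.

library(megentrain)

RESULTS_DIR <- "results"
CACHE_DIR <- file.path("scratch", "analysis_cache")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE_DIR, showWarnings = FALSE, recursive = TRUE)

# Demonstration cohort: 8 subjects per group, 40 trials, 16 sensors, 64
# voxels, with the study's effect pattern baked into the ground truth
# (equal absolute amplitude, ADS baseline 15 Hz and cross-trial CV lower,
# positive amplitude-to-cognition link).
MASTER_SEED <- 20260921
CFG <- default_config(master_seed = MASTER_SEED)

cache_path <- function(name) file.path(CACHE_DIR, paste0(name, ".rds"))
save_stage <- function(obj, name) saveRDS(obj, cache_path(name))
load_stage <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p)) stop("run the earlier analysis scripts first: missing ", p)
  readRDS(p)
}
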
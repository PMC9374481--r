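#!/usr/bin/env Rscript
# Stage 3: sensor-level time-frequency maps and permutation selection of
# the entrainment time-frequency window.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

cohort <- load_stage("02_cohort_clean")
maps <- lapply(cohort$subjects, function(s) sensor_relative_power(s$epochs))
mask <- select_entrainment_window(
  maps, alpha = CFG$window_select$alpha, n_perm = CFG$window_select$n_perm,
  seed = megentrain:::derive_seed(CFG$synth$master_seed, 1000003L),
  freqs = tfr_freqs(), times = tfr_times(),
  valid_frames = tfr_frame_support() >= CFG$window_select$min_support)

m <- mask$mask
write.csv(data.frame(freq = rep(as.numeric(rownames(m)), ncol(m)),
                     time = rep(as.numeric(colnames(m)), each = nrow(m)),
                     selected = as.vector(m)),
          file.path(RESULTS_DIR, "significance_mask.csv"), row.names = FALSE)
write.csv(mask$clusters, file.path(RESULTS_DIR, "mask_clusters.csv"),
          row.names = FALSE)
save_stage(list(maps = maps, mask = mask), "03_sensor_tfr")

row15 <- tfr_times()[m["15", ]]
message(sprintf("%d of %d bins selected at corrected p < %g (%d permutations)",
                sum(m), length(m), CFG$window_select$alpha,
                CFG$window_select$n_perm))
message(sprintf("15 Hz row spans %d to %d ms (response window 200-2000 ms plus ~filter half-width)",
                min(row15), max(row15)))
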
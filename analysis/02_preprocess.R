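#!/usr/bin/env Rscript
# Stage 2: individualized amplitude/gradient artifact rejection.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

cohort <- load_stage("01_cohort")
rows <- list()
for (i in seq_along(cohort$subjects)) {
  s <- cohort$subjects[[i]]
  rr <- reject_artifacts(s$epochs, CFG$preprocess$k_amp, CFG$preprocess$k_grad)
  cohort$subjects[[i]]$epochs <- rr$epochs
  rows[[i]] <- data.frame(subject = s$subject_id, group = s$group,
                          amp_threshold = rr$report$amp_threshold,
                          grad_threshold = rr$report$grad_threshold,
                          n_kept = rr$report$n_kept,
                          n_rejected = rr$report$n_rejected,
                          n_true_artifacts = sum(s$ground_truth$artifact_trials))
}
rej <- do.call(rbind, rows)
write.csv(rej, file.path(RESULTS_DIR, "rejection_report.csv"), row.names = FALSE)
save_stage(cohort, "02_cohort_clean")

message(sprintf("rejected %d / %d trials across the cohort (%.1f%% mean per subject)",
                sum(rej$n_rejected), sum(rej$n_kept + rej$n_rejected),
                100 * mean(rej$n_rejected / (rej$n_kept + rej$n_rejected))))
message(sprintf("%d planted artifact trials in the generator; %d trials flagged",
                sum(rej$n_true_artifacts), sum(rej$n_rejected)))
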
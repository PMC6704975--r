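#!/usr/bin/env Rscript
# Step 2: signal conditioning.
#
# Each recording is band-pass filtered 1-40 Hz (zero-phase Butterworth),
# would be decimated to 125 Hz had it been sampled faster, and re-referenced
# to the average reference. The first and last second are flagged as filter
# edge transients so GFP-peak extraction skips them.

suppressMessages(library(microstater))

if (!file.exists("scratch/cohort.rds"))
  stop("run analysis/01_simulate.R first")
cohort <- readRDS("scratch/cohort.rds")

recs <- lapply(cohort$subjects, function(s) {
  r <- bandpass_filter(s$recording, 1, 40)
  average_reference(r)
})
saveRDS(recs, "scratch/preprocessed.rds")

gfp_means <- vapply(recs, function(r) mean(compute_gfp(r)$values), numeric(1))
n_peaks <- vapply(recs, function(r) length(find_gfp_peaks(compute_gfp(r))),
                  numeric(1))
message(sprintf("Preprocessed %d recordings; mean GFP %.3g, %.0f GFP peaks/subject (%.1f peaks/s).",
                length(recs), mean(gfp_means), mean(n_peaks),
                mean(n_peaks) / 298))
write.csv(data.frame(subject = vapply(recs, `[[`, "", "subject"),
                     mean_gfp = gfp_means, n_gfp_peaks = n_peaks),
          "results/preprocess_summary.csv", row.names = FALSE)
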
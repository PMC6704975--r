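#!/usr/bin/env Rscript
# Step 5: group and clinical statistics.
#
# Independent t-tests (FDR-corrected within each parameter family) compare
# the patient-tagged and control-tagged halves of the cohort; the simulation
# plants no group difference, so discoveries here are false positives at the
# nominal familywise rate (and at 5 subjects per group the tests are noisy —
# the calibration experiments in the test suite use realistic group sizes).
# A synthetic clinical table (MADRS, CGI, episode count, medication scale)
# with one planted monotone association then illustrates the Spearman
# correlation stage at alpha = 0.01.

suppressMessages(library(microstater))

if (!file.exists("scratch/metrics.rds"))
  stop("run analysis/04_segment.R first")
metrics <- readRDS("scratch/metrics.rds")

tests <- group_ttests(metrics)
write.csv(tests, "results/group_tests.csv", row.names = FALSE)
message(sprintf("Group t-tests: %d cells, min FDR-adjusted p = %.2f (no planted difference).",
                nrow(tests), min(tests$p_fdr, na.rm = TRUE)))

# synthetic clinical covariates for the patient-tagged subjects; the MADRS
# column is constructed to track occurrence of class A so one cell must flag
set.seed(2)
pats <- sort(unique(metrics$subject[metrics$group == "patient"]))
occA <- metrics$occurrence_per_s[metrics$group == "patient" &
                                   metrics$class == "A"]
occA <- occA[match(pats, metrics$subject[metrics$group == "patient" &
                                           metrics$class == "A"])]
clinical <- data.frame(
  subject = pats,
  madrs = round(10 + 28 * rank(occA) / length(occA)),
  cgi = sample(3:6, length(pats), replace = TRUE),
  n_episodes = sample(1:5, length(pats), replace = TRUE),
  medication_scale = sample(1:4, length(pats), replace = TRUE))
write.csv(clinical, "results/clinical_synthetic.csv", row.names = FALSE)

corrs <- correlate_with_clinical(metrics, clinical, alpha = 0.01)
write.csv(corrs, "results/clinical_correlations.csv", row.names = FALSE)
sig <- corrs[corrs$significant, ]
message(sprintf("Clinical correlations: %d cells tested, %d significant at alpha 0.01.",
                nrow(corrs), nrow(sig)))
if (nrow(sig))
  message(paste(sprintf("  %s of class %s vs %s: rho = %.2f (p = %.2g)",
                        sig$parameter, sig$class, sig$variable, sig$rho, sig$p),
                collapse = "\n"))
message("Tables -> results/group_tests.csv, results/clinical_correlations.csv")
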
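#!/usr/bin/env Rscript
# Statistical calibration of the group comparison: type-I error under null
# group effects, and detection of an injected heterogeneity offset pushed
# through the full voxel pipeline (log-logistic field, Rician multi-echo
# decay, T2 mapping, capping, MLE). Reduced replicate counts keep this
# script quick; the test suite runs the full-size versions.

suppressPackageStartupMessages(library(t2het))
dir.create("results", showWarnings = FALSE)

cal <- type1_calibration(n_rep = 200, seed = 161803L)
cat(sprintf("Type-I error at alpha = 0.05: %.3f (%d null cohorts)\n",
            cal$rejection_rate, cal$n_rep))

reps <- lapply(1:25, function(r)
  effect_recovery_replicate(delta_sigma = 0.02, n_hc = 97, n_mci = 49,
                            n_voxels = 3000, snr = 50, seed = 97000 + r * 13L))
power <- mean(vapply(reps, `[[`, 0, "p") < 0.05)
mean_raw <- mean(vapply(reps, `[[`, 0, "diff_raw"))
mean_emm <- mean(vapply(reps, `[[`, 0, "diff_emm"))
cat(sprintf("Injected MCI-HC delta sigma = 0.02: detected in %.0f%% of %d replicates\n",
            100 * power, length(reps)))
cat(sprintf("Mean recovered difference: raw %.4f, age-adjusted %.4f\n",
            mean_raw, mean_emm))
cat("The age-adjusted estimate runs slightly low: the physiological caps\n",
    "truncate the upper T2 tail, which shrinks fitted heterogeneity more\n",
    "for the wider MCI distributions.\n", sep = "")

write.csv(data.frame(
  quantity = c("type1_rate", "power", "mean_diff_raw", "mean_diff_emm"),
  value = c(cal$rejection_rate, power, mean_raw, mean_emm),
  n_rep = c(cal$n_rep, length(reps), length(reps), length(reps))),
  "results/calibration.csv", row.names = FALSE)
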
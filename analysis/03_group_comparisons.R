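#!/usr/bin/env Rscript
# Group comparisons at full cohort scale (97 HC / 49 MCI / 10 AD):
# z-normalize each metric to the per-study healthy-control reference, then
# ANCOVA with age as covariate, estimated marginal means, Sidak-corrected
# pairwise tests and Levene's variance check, for T2sigma, T2mu and
# ICV-corrected volume.

suppressPackageStartupMessages(library(t2het))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = 314159L)   # defaults: MCI sigma +0.02, AD mu +0.03
cm <- simulate_cohort_metrics(spec)

metrics <- list(
  T2sigma = cm$T2sigma_hippocampus,
  T2mu = cm$T2mu_hippocampus,
  volume = icv_correct(cm$vol_hippocampus_mm3, cm$icv_mm3))

rows <- list()
for (nm in names(metrics)) {
  z <- zscore_to_reference(metrics[[nm]], cm$group == "HC", cm$study)
  a <- ancova_group(z, cm$group, data.frame(age = cm$age))
  cat(sprintf("\n%s: F(%d, %d) = %.2f, p = %.4g; Levene p = %.2f\n",
              nm, a$df1, a$df2, a$F, a$p, a$levene$p))
  for (j in seq_len(nrow(a$pairwise)))
    cat(sprintf("  %-10s p_sidak = %.4g\n", a$pairwise$pair[j],
                a$pairwise$p_sidak[j]))
  rows[[nm]] <- cbind(metric = nm, a$pairwise,
                      F = a$F, df1 = a$df1, df2 = a$df2, p_group = a$p,
                      levene_p = a$levene$p)
}
write.csv(do.call(rbind, rows), "results/group_comparisons.csv",
          row.names = FALSE)

cat("\nUnder the default generator the heterogeneity (T2sigma) contrast\n",
    "separates MCI from controls while the midpoint (T2mu) contrast is\n",
    "driven by the small AD group - the pattern the marker is designed\n",
    "to exhibit.\n", sep = "")
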
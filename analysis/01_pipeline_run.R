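#!/usr/bin/env Rscript
# End-to-end phantom run: simulate a 20-subject multi-echo cohort, map T2,
# extract capped ROI samples, fit distribution families, and run the
# cohort statistics. Outputs land under results/pipeline/.

suppressPackageStartupMessages(library(t2het))

out_dir <- "results/pipeline"
config <- list(
  group_sizes = c(HC = 10, MCI = 8, AD = 2),
  grid_shape = c(32, 32, 16),
  echo_preset = "cpmg10",     # TE 12..120 ms, first echo excluded
  noise_sd = 20,              # SNR 50 at s0 = 1000
  families = "default18",
  seed = 7L)

t0 <- proc.time()[["elapsed"]]
manifest <- run_pipeline(config, out_dir)
elapsed <- proc.time()[["elapsed"]] - t0

res <- jsonlite::read_json(file.path(out_dir, "stats", "results.json"),
                           simplifyVector = TRUE)
cat(sprintf("\nFull run of %d subjects finished in %.1f s.\n",
            sum(config$group_sizes), elapsed))
cat(sprintf("Modal best-fitting family (hippocampus): %s\n",
            res$modal_family$hippocampus))
a <- res$ancova$hippocampus$T2sigma
cat(sprintf("Group effect on T2sigma: F(%d, %d) = %.2f, p = %.3f\n",
            a$df1, a$df2, a$F, a$p))
cat("Stage timings (s):\n")
for (s in names(manifest$stages))
  cat(sprintf("  %-8s %6.1f\n", s, manifest$stages[[s]]$seconds))
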
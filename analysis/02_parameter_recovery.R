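#!/usr/bin/env Rscript
# Parameter recovery of the log-logistic MLE: refit large seeded samples
# drawn at the two worked-example parameter pairs (healthy control and
# MCI), and trace how estimation error shrinks with sample size.

suppressPackageStartupMessages(library(t2het))
dir.create("results", showWarnings = FALSE)

examples <- list(HC = c(mu = 4.68, sigma = 0.112),
                 MCI = c(mu = 4.71, sigma = 0.135))

rows <- list()
for (nm in names(examples)) {
  p <- examples[[nm]]
  set.seed(20200910 + match(nm, names(examples)))
  f <- fit_loglogistic_mle(rloglogis(1e5, p[["mu"]], p[["sigma"]]))
  rows[[nm]] <- data.frame(example = nm, n = 1e5,
                           mu_true = p[["mu"]], mu_hat = f$mu,
                           sigma_true = p[["sigma"]], sigma_hat = f$sigma)
  cat(sprintf("%-3s: mu %.4f -> %.4f, sigma %.4f -> %.4f (n = 1e5)\n",
              nm, p[["mu"]], f$mu, p[["sigma"]], f$sigma))
}
write.csv(do.call(rbind, rows), "results/parameter_recovery.csv",
          row.names = FALSE)

# consistency curve: RMSE over 50 seeded replicates at three sample sizes
cons <- do.call(rbind, lapply(c(100, 1000, 10000), function(n) {
  errs <- sapply(1:50, function(r) {
    set.seed(n + r)
    f <- fit_loglogistic_mle(rloglogis(n, 4.68, 0.112))
    c(f$mu - 4.68, f$sigma - 0.112)
  })
  data.frame(n = n, rmse_mu = sqrt(mean(errs[1, ]^2)),
             rmse_sigma = sqrt(mean(errs[2, ]^2)))
}))
write.csv(cons, "results/mle_consistency.csv", row.names = FALSE)
cat("\nRMSE by sample size (50 replicates each):\n")
print(cons, row.names = FALSE)
cat("Estimation error falls with n, as consistency requires.\n")
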
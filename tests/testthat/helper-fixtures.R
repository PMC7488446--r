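# Small in-code fixtures shared across test files.

tiny_cohort_spec <- function(...) {
  cohort_spec(group_sizes = c(HC = 6, MCI = 5, AD = 3), ...)
}

tiny_phantom <- function(noise_model = "none", ...) {
  phantom_spec(grid_shape = c(16L, 16L, 8L), noise_model = noise_model, ...)
}

# subject truth row for a single hippocampus region
truth_row <- function(mu = 4.68, sigma = 0.112, region = "hippocampus") {
  data.frame(region = region, mu_true = mu, sigma_true = sigma,
             stringsAsFactors = FALSE)
}

# independent normal-equations OLS oracle: solve (X'X) b = X'y explicitly
ols_oracle <- function(X, y) {
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
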
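test_that("cohort table has the configured structure and is deterministic", {
  spec <- cohort_spec()  # defaults: 97/49/10
  tab <- generate_cohort_table(spec)
  expect_equal(nrow(tab), 156)
  expect_equal(as.vector(table(tab$group)), c(97, 49, 10))
  expect_equal(sum(tab$sex == "M"), 46 + 27 + 2)
  expect_true(all(tab$age >= 40 & tab$age <= 100))
  # AD subjects belong to study 1 only
  expect_true(all(tab$study[tab$group == "AD"] == "study1"))
  expect_identical(tab, generate_cohort_table(spec))
  # empty cohort is not an error
  empty <- generate_cohort_table(cohort_spec(group_sizes = c(HC = 0, MCI = 0, AD = 0)))
  expect_equal(nrow(empty), 0)
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(age_sd = c(HC = -1, MCI = 1, AD = 1)), "age_sd")
  expect_error(cohort_spec(regions = list(h = region_params(sigma0 = -0.1))),
               "sigma0")
  # a sigma slope that goes negative inside the age range is rejected
  expect_error(cohort_spec(regions = list(h = region_params(slope_sigma_age = 0.01))),
               "non-positive heterogeneity")
})

test_that("subject parameters follow the linear group/age model", {
  null_spec <- cohort_spec(regions = list(hippocampus = region_params(
    delta_mu = c(HC = 0, MCI = 0, AD = 0),
    delta_sigma = c(HC = 0, MCI = 0, AD = 0),
    slope_mu_age = 0, slope_sigma_age = 0)))
  row <- data.frame(group = "AD", age = 93)
  p <- sample_subject_t2_params(row, null_spec)
  expect_equal(p$mu_true, 4.68)
  expect_equal(p$sigma_true, 0.113)

  # default spec reproduces the worked healthy-control example at age 69
  p69 <- sample_subject_t2_params(data.frame(group = "HC", age = 69),
                                  cohort_spec())
  expect_equal(p69$mu_true, 4.68)
  expect_equal(p69$sigma_true, 0.112)

  # slope arithmetic: 0.001/yr over 20 years = 0.02
  sl <- cohort_spec(regions = list(h = region_params(slope_sigma_age = 0.001)))
  s60 <- sample_subject_t2_params(data.frame(group = "HC", age = 60), sl)$sigma_true
  s80 <- sample_subject_t2_params(data.frame(group = "HC", age = 80), sl)$sigma_true
  expect_equal(s80 - s60, 0.02)
})

test_that("injected group offsets appear exactly in the truth table", {
  spec <- cohort_spec(group_sizes = c(HC = 40, MCI = 30, AD = 10))
  tab <- generate_cohort_table(spec)
  truth <- cohort_truth(tab, spec)
  rp <- spec$regions$hippocampus
  # remove the age term; what remains is baseline + group delta, exactly
  resid <- truth$sigma_true - rp$slope_sigma_age * (truth$age - 70)
  for (g in c("HC", "MCI", "AD"))
    expect_lt(abs(mean(resid[truth$group == g]) -
                    (rp$sigma0 + rp$delta_sigma[[g]])), 1e-12)
})

test_that("rendered T2 fields realize the target distribution", {
  ph <- tiny_phantom()
  fld <- render_t2_field(truth_row(4.68, 0.112), ph, seed = 3)
  ml <- fld$masks$hippocampus$left
  mr <- fld$masks$hippocampus$right
  expect_equal(sum(ml & mr), 0)  # hemispheres disjoint
  expect_true(all(fld$t2 > 0))
  # background voxels keep the configured constant
  expect_true(all(fld$t2[!(ml | mr)] == ph$background_t2))

  # sigma -> 0 collapses the field onto exp(mu)
  fld0 <- render_t2_field(truth_row(4.68, 1e-6), ph, seed = 4)
  expect_equal(max(abs(fld0$t2[ml] - exp(4.68))), 0, tolerance = 1e-3)

  # large-sample median within 1% of exp(mu) (quantile oracle)
  set.seed(9)
  xs <- rloglogis_bounded(1e5, 4.68, 0.112)
  expect_lt(abs(median(xs) / exp(4.68) - 1), 0.01)

  # KS distance of bounded draws against the target CDF
  ks <- suppressWarnings(ks.test(xs, ploglogis, mu = 4.68, sigma = 0.112))
  expect_lt(unname(ks$statistic), 0.01)
  expect_true(all(xs >= 1 & xs <= 1000))
})

test_that("multi-echo simulation follows the mono-exponential signal model", {
  ph <- tiny_phantom(noise_model = "none")
  t2 <- array(100, dim = c(2, 2, 2))
  img <- simulate_multi_echo(t2, ph, seed = 1)
  # closed form at TE = 12 ms, s0 = 1000
  expect_equal(img$signal[1, 1, 1, 1], 1000 * exp(-0.12), tolerance = 1e-12)
  # strict monotone decay across echoes, all below s0
  expect_true(all(diff(img$signal[, 1, 1, 1]) < 0))
  expect_true(all(img$signal < 1000))

  # rician magnitudes are strictly positive; gaussian can cross zero
  ph_r <- tiny_phantom(noise_model = "rician", noise_sd = 500)
  expect_true(all(simulate_multi_echo(t2, ph_r, seed = 2)$signal > 0))

  # zero-signal rician noise is Rayleigh: mean sigma*sqrt(pi/2)
  set.seed(5)
  r <- sqrt(rnorm(1e5)^2 + rnorm(1e5)^2)
  expect_equal(mean(r), sqrt(pi / 2), tolerance = 0.01)

  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(echo_times = c(10, 10, 20)), "strictly increasing")
})

test_that("noiseless simulate/map round-trip recovers every voxel exactly", {
  ph <- tiny_phantom(noise_model = "none")
  fld <- render_t2_field(truth_row(4.7, 0.12), ph, seed = 6)
  img <- simulate_multi_echo(fld$t2, ph, seed = 7)
  map <- compute_t2_map(img)
  expect_true(all(map$valid))
  expect_lt(max(abs(map$t2 - fld$t2) / fld$t2), 1e-6)
})

test_that("generators are pure functions of spec and seed", {
  ph <- tiny_phantom(noise_model = "rician")
  a <- render_t2_field(truth_row(), ph, seed = 8)
  b <- render_t2_field(truth_row(), ph, seed = 8)
  expect_identical(a, b)
  ia <- simulate_multi_echo(a$t2, ph, seed = 9)
  ib <- simulate_multi_echo(b$t2, ph, seed = 9)
  expect_identical(ia$signal, ib$signal)
})

test_that("cognition follows the linear generating model", {
  spec <- tiny_cohort_spec()
  tab <- generate_cohort_table(spec)
  truth <- cohort_truth(tab, spec)

  # zero marker effect and zero noise: follow-up is an exact affine function
  co <- spec$cognition
  co$beta_sigma <- 0; co$error_sd <- 0
  c1 <- simulate_cognition(tab, truth, co, seed = 10)
  pred <- co$intercept + co$beta_age * c1$age + co$beta_baseline * c1$cog_baseline
  expect_equal(c1$cog_followup, pred, tolerance = 1e-12)

  # determinism
  c2 <- simulate_cognition(tab, truth, spec$cognition, seed = 11)
  c3 <- simulate_cognition(tab, truth, spec$cognition, seed = 11)
  expect_identical(c2$cog_followup, c3$cog_followup)

  # negative beta_sigma induces a negative partial correlation with sigma
  big <- cohort_spec(group_sizes = c(HC = 100, MCI = 100, AD = 0))
  btab <- generate_cohort_table(big)
  btruth <- cohort_truth(btab, big)
  co2 <- big$cognition; co2$beta_sigma <- -30
  c4 <- simulate_cognition(btab, btruth, co2, seed = 12)
  sg <- btruth$sigma_true[match(c4$subject_id, btruth$subject_id)]
  pred0 <- co2$intercept + co2$beta_age * c4$age + co2$beta_baseline * c4$cog_baseline
  expect_lt(cor(sg, c4$cog_followup - pred0), 0)

  # missing truth rows are a schema error
  expect_error(simulate_cognition(tab, truth[-1, ], spec$cognition, seed = 1),
               "schema error")
})

test_that("subject-level metric simulator injects effects without confounding", {
  spec <- cohort_spec(group_sizes = c(HC = 200, MCI = 200, AD = 0))
  cm <- simulate_cohort_metrics(spec, subject_sd_mu = 0,
                                subject_sd_sigma = 0, seed = 77)
  truth <- attr(cm, "truth")
  # configured delta equals the group difference of age-detrended truth
  rp <- spec$regions$hippocampus
  det <- truth$sigma_true - rp$slope_sigma_age * (truth$age - 70)
  gap <- mean(det[truth$group == "MCI"]) - mean(det[truth$group == "HC"])
  expect_lt(abs(gap - rp$delta_sigma[["MCI"]]), 1e-12)
  # with zero dispersion the observed metric equals the truth
  expect_equal(cm$T2sigma_hippocampus,
               truth$sigma_true[match(cm$subject_id, truth$subject_id)])
})
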
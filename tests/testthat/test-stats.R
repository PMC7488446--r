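test_that("reference z-scoring centres and scales each study's reference group", {
  expect_equal(zscore_to_reference(c(1, 2, 3), c(TRUE, TRUE, TRUE)),
               c(-1, 0, 1))
  # two studies on different raw scales: each reference ends at mean 0, SD 1
  set.seed(71)
  study <- rep(c("s1", "s2"), each = 40)
  ref <- rep(c(TRUE, FALSE), 40)
  x <- ifelse(study == "s1", rnorm(80, 25, 3), rnorm(80, 90, 12))
  z <- zscore_to_reference(x, ref, study)
  for (s in c("s1", "s2")) {
    expect_lt(abs(mean(z[study == s & ref])), 1e-12)
    expect_lt(abs(sd(z[study == s & ref]) - 1), 1e-12)
  }
  expect_lt(abs(mean(z[ref])), 1e-12)  # pooled reference mean still 0
  expect_error(zscore_to_reference(1:4, c(TRUE, FALSE, FALSE, FALSE)),
               "fewer than 2")
  expect_error(zscore_to_reference(c(1, 1, 2), c(TRUE, TRUE, FALSE)),
               "zero reference SD")
})

test_that("ICV correction: ratio default, residual regression option", {
  expect_equal(icv_correct(3000, 1.5e6), 0.002)
  # equal volumes, different ICVs invert the ordering
  cv <- icv_correct(c(3000, 3000), c(1.4e6, 1.6e6))
  expect_true(cv[1] > cv[2])
  expect_error(icv_correct(3000, -1), "icv must be")
  # residual method: ICV-independent volumes give (near) zero slope removal
  set.seed(72)
  icv <- rnorm(200, 1.5e6, 1e5)
  vol <- rnorm(200, 3200, 300)
  res <- icv_correct(vol, icv, method = "residual")
  expect_lt(abs(coef(lm(res ~ icv))[2]), 1e-3)
  expect_equal(mean(res), mean(vol))
})

test_that("ANCOVA reports the canonical degrees of freedom", {
  set.seed(73)
  n <- c(97, 49, 10)
  grp <- factor(rep(c("HC", "MCI", "AD"), n), levels = c("HC", "MCI", "AD"))
  age <- rnorm(156, 70, 9)
  y <- rnorm(156) + 0.3 * (grp == "MCI")
  a <- ancova_group(y, grp, data.frame(age = age))
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 152)
  expect_equal(nrow(a$pairwise), 3)
  expect_true(all(a$pairwise$p_sidak >= a$pairwise$p_raw))
})

test_that("ANCOVA F matches the explicit nested-model RSS computation", {
  set.seed(74)
  for (r in 1:100) {
    n <- sample(15:40, 1)
    g <- sample(2:3, 1)
    grp <- factor(sample(letters[1:g], n, replace = TRUE))
    while (any(table(grp) < 2) || nlevels(droplevels(grp)) < g)
      grp <- factor(sample(letters[1:g], n, replace = TRUE))
    age <- rnorm(n, 70, 8)
    y <- rnorm(n) + 0.5 * as.integer(grp) + 0.02 * age
    a <- ancova_group(y, grp, data.frame(age = age))
    # oracle: raw design matrices, dummy coding (F is coding-invariant)
    X1 <- model.matrix(~ grp + age)
    X0 <- model.matrix(~ age)
    rss1 <- sum(lm.fit(X1, y)$residuals^2)
    rss0 <- sum(lm.fit(X0, y)$residuals^2)
    Fo <- ((rss0 - rss1) / (g - 1)) / (rss1 / (n - g - 1))
    expect_equal(a$F, Fo, tolerance = 1e-8)
  }
})

test_that("ANCOVA agrees with the car Type-III oracle", {
  skip_if_not_installed("car")
  set.seed(75)
  grp <- factor(rep(c("HC", "MCI", "AD"), c(30, 20, 10)))
  age <- rnorm(60, 70, 8)
  y <- rnorm(60) + 0.5 * (grp == "AD") + 0.03 * age
  a <- ancova_group(y, grp, data.frame(age = age))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  ca <- car::Anova(lm(y ~ grp + age), type = 3)
  expect_equal(a$F, ca["grp", "F value"], tolerance = 1e-10)
  expect_equal(a$p, ca["grp", "Pr(>F)"], tolerance = 1e-10)
})

test_that("covariate orthogonal to group and outcome reduces to one-way ANOVA", {
  set.seed(76)
  grp <- factor(rep(c("a", "b", "c"), each = 20))
  y <- rnorm(60) + as.integer(grp)
  cov_orth <- residuals(lm(rnorm(60) ~ grp + y))  # orthogonal by construction
  a <- ancova_group(y, grp, data.frame(c1 = cov_orth))
  f1 <- summary(aov(y ~ grp))[[1]]$`F value`[1]
  # same numerator; denominator df differs by the covariate's one df
  rss <- sum(residuals(lm(y ~ grp))^2)
  expect_equal(a$F * (rss / a$df2) / (rss / 57), f1, tolerance = 1e-8)
})

test_that("mirrored groups give exactly zero group effect", {
  set.seed(77)
  y0 <- rnorm(30); age0 <- rnorm(30, 70, 5)
  y <- c(y0, y0); age <- c(age0, age0)
  grp <- factor(rep(c("a", "b"), each = 30))
  a <- ancova_group(y, grp, data.frame(age = age))
  expect_equal(a$F, 0, tolerance = 1e-20)
  expect_equal(a$emm$emm[1], a$emm$emm[2])
})

test_that("estimated marginal means average out the covariate at its grand mean", {
  set.seed(78)
  grp <- factor(rep(c("a", "b"), each = 40))
  age <- rnorm(80, 70, 8)
  y <- 2 + 1 * (grp == "b") + 0.1 * age + rnorm(80, 0, 0.2)
  a <- ancova_group(y, grp, data.frame(age = age))
  fit <- lm(y ~ grp + age)
  pred <- predict(fit, newdata = data.frame(grp = factor(c("a", "b")),
                                            age = mean(age)))
  expect_equal(a$emm$emm, unname(pred), tolerance = 1e-10)
})

test_that("Sidak correction is exact, monotone and bounded", {
  expect_equal(sidak_pairwise(0.05, 3), 1 - 0.95^3)  # 0.142625
  expect_equal(sidak_pairwise(0.05, 3), 0.142625)
  expect_equal(sidak_pairwise(0.2, 1), 0.2)
  expect_equal(sidak_pairwise(0, 5), 0)
  expect_equal(sidak_pairwise(1, 2), 1)
  p <- 0.03
  expect_true(all(diff(sidak_pairwise(p, 1:10)) > 0))
  expect_true(all(sidak_pairwise(c(0.1, 0.5), 4) >= c(0.1, 0.5)))
  expect_error(sidak_pairwise(1.2, 2), "\\[0, 1\\]")
})

test_that("Levene's test matches the ANOVA-on-deviations oracle", {
  y <- c(0, 2, -10, 10)
  g <- factor(c("a", "a", "b", "b"))
  # two points per group make the deviation fit exact; the F warning is expected
  lv <- suppressWarnings(levene_test(y, g))
  d <- abs(y - ave(y, g))
  or <- suppressWarnings(summary(aov(d ~ g))[[1]])
  expect_equal(lv$W, or$`F value`[1], tolerance = 1e-12)
  expect_equal(lv$p, or$`Pr(>F)`[1], tolerance = 1e-12)

  # mirror-copied spreads: deviation profiles identical in both groups, W = 0
  y2 <- c(1, 3, 5, 11, 13, 15)
  g2 <- factor(rep(c("a", "b"), each = 3))
  expect_equal(levene_test(y2, g2)$W, 0)

  # scale invariance
  set.seed(79)
  y3 <- rnorm(40); g3 <- factor(rep(c("a", "b"), 20))
  expect_equal(levene_test(y3, g3)$W, levene_test(y3 * 7.3, g3)$W,
               tolerance = 1e-12)
  expect_error(levene_test(c(1, 2, 3), factor(c("a", "a", "b"))), "n >= 2")
})

test_that("Levene agrees with the car oracle for both centres", {
  skip_if_not_installed("car")
  set.seed(80)
  y <- rnorm(90, 0, rep(c(1, 2, 3), 30))
  g <- factor(rep(c("a", "b", "c"), 30))
  mine <- levene_test(y, g, center = "mean")
  ref <- car::leveneTest(y, g, center = mean)
  expect_equal(mine$W, ref$`F value`[1], tolerance = 1e-12)
  mine_m <- levene_test(y, g, center = "median")
  ref_m <- car::leveneTest(y, g, center = median)
  expect_equal(mine_m$W, ref_m$`F value`[1], tolerance = 1e-12)
})

test_that("follow-up regression reports standardized betas and F(3, n-4)", {
  set.seed(81)
  n <- 20
  age <- rnorm(n, 72, 8); bl <- rnorm(n); mk <- rnorm(n)
  y <- -0.5 * mk + 0.6 * bl + rnorm(n, 0, 0.5)
  fr <- followup_regression(y, age, bl, mk, marker_name = "T2sigma")
  expect_equal(fr$df1, 3)
  expect_equal(fr$df2, 16)
  expect_equal(fr$n, 20)
  # standardized betas equal lm on scale()d variables
  ref <- lm(scale(y) ~ scale(age) + scale(bl) + scale(mk))
  expect_equal(fr$coefficients$beta, unname(coef(ref))[-1], tolerance = 1e-10)
  expect_equal(fr$r2, summary(ref)$r.squared, tolerance = 1e-12)
  # overall F identity with R^2
  expect_equal(fr$F, (fr$r2 / 3) / ((1 - fr$r2) / 16), tolerance = 1e-12)

  # zero marker coefficient, zero noise: recovered beta is numerically zero
  y0 <- 1.3 * age + 0.6 * bl
  fr0 <- suppressWarnings(followup_regression(y0, age, bl, mk))
  expect_lt(abs(fr0$coefficients$beta[3]), 1e-10)

  expect_error(followup_regression(y[1:4], age[1:4], bl[1:4], mk[1:4]), "n >")
})

test_that("negative generating beta is recovered with the right sign", {
  # subjects with heterogeneity variation beyond the age trend, so the
  # age-adjusted marker coefficient is identified
  spec <- cohort_spec(group_sizes = c(HC = 0, MCI = 200, AD = 0))
  tab <- generate_cohort_table(spec)
  co <- spec$cognition  # beta_sigma = -30
  hits <- sapply(1:100, function(r) {
    set.seed(9000 + r)
    truth <- data.frame(subject_id = tab$subject_id, region = "hippocampus",
                        sigma_true = 0.133 + 0.001 * (tab$age - 70) +
                          rnorm(nrow(tab), 0, 0.02))
    cm <- simulate_cognition(tab, truth, co, seed = 50000 + r)
    marker <- truth$sigma_true[match(cm$subject_id, truth$subject_id)]
    fr <- followup_regression(cm$cog_followup, cm$age, cm$cog_baseline, marker)
    fr$coefficients$beta[3] < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("partial residuals satisfy the Frisch-Waugh identity", {
  set.seed(82)
  n <- 50
  age <- rnorm(n, 70, 9); bl <- rnorm(n); mk <- 0.5 * age + rnorm(n)
  y <- 0.3 * age - 0.4 * bl - 2 * mk + rnorm(n)
  pr <- partial_residuals(y, age, bl, mk)
  full <- lm(y ~ age + bl + mk)
  expect_equal(pr$slope, unname(coef(full)["mk"]), tolerance = 1e-8)
  expect_equal(sd(pr$x_resid), 1, tolerance = 1e-12)
  expect_equal(sd(pr$y_resid), 1, tolerance = 1e-12)

  # marker unrelated to outcome given covariates: slope near zero
  mk0 <- rnorm(n)
  y0 <- 0.3 * age - 0.4 * bl + rnorm(n)
  pr0 <- partial_residuals(y0, age, bl, mk0)
  expect_equal(unname(coef(lm(pr0$y_resid_raw ~ pr0$x_resid_raw))[2]),
               unname(coef(lm(y0 ~ age + bl + mk0))["mk0"]), tolerance = 1e-8)
})

test_that("age regression matches the Pearson correlation identity", {
  age <- seq(50, 90, length.out = 20)
  ar <- suppressWarnings(age_regression(2 * age, age))
  expect_equal(ar$r2, 1)
  expect_equal(ar$slope, 2)

  set.seed(83)
  age2 <- rnorm(97, 70, 8)
  m <- rnorm(97)
  ar2 <- age_regression(m, age2)
  expect_equal(ar2$r2, cor(m, age2)^2, tolerance = 1e-12)
  expect_lt(ar2$r2, 0.1)
  expect_error(age_regression(m, rep(70, 97)), "constant")
  expect_error(age_regression(1:2, 1:2), "n >= 3")
})

test_that("injected age slope is recovered with the right sign", {
  hits <- sapply(1:100, function(r) {
    set.seed(7000 + r)
    age <- rnorm(97, 70, 8.6)
    sigma <- 0.113 + 0.001 * (age - 70) + rnorm(97, 0, 0.023)
    age_regression(sigma, age)$slope > 0
  })
  expect_gte(mean(hits), 0.95)
})
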
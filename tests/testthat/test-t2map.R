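test_that("log-linear fit matches closed forms", {
  # exact exponential: recovered T2 is machine-precision exact
  te <- seq(24, 120, by = 12)
  f <- log_linear_fit(exp(-te / 80), te)
  expect_lt(abs(f$t2 - 80), 1e-9)
  expect_equal(f$r2, 1)
  expect_true(f$valid)

  # two-echo closed form: T2 = dTE / log(S1/S2)
  f2 <- log_linear_fit(c(1.0, 0.5), c(12, 24))
  expect_equal(f2$t2, 12 / log(2), tolerance = 1e-12)

  expect_error(log_linear_fit(c(1, 0.5), c(12, 24, 36)), "equal length")
})

test_that("first-echo exclusion drops echo 1 and matches the 9-point OLS oracle", {
  set.seed(41)
  te <- seq(12, 120, by = 12)
  s <- 900 * exp(-te / 95) * exp(rnorm(10, 0, 0.02))
  s[1] <- s[1] * 1.4  # corrupt the first echo; it must not matter
  f <- log_linear_fit(s, te, exclude_first = TRUE)
  b <- ols_oracle(cbind(1, te[-1]), log(s[-1]))
  expect_equal(f$t2, -1 / b[2], tolerance = 1e-10)
  expect_equal(f$s0, exp(b[1]), tolerance = 1e-10)
})

test_that("fit equals the normal-equations oracle on random inputs", {
  set.seed(42)
  for (r in 1:50) {
    ne <- sample(3:12, 1)
    te <- sort(runif(ne, 5, 200))
    t2 <- runif(1, 30, 200)
    s <- runif(1, 100, 2000) * exp(-te / t2) * exp(rnorm(ne, 0, 0.05))
    f <- log_linear_fit(s, te)
    b <- ols_oracle(cbind(1, te), log(s))
    expect_equal(f$t2, -1 / b[2], tolerance = 1e-10)
  }
})

test_that("invalidity contract: nonpositive signals and rising series", {
  te <- c(12, 24, 36)
  expect_false(log_linear_fit(c(1, 0, 0.2), te)$valid)
  expect_false(log_linear_fit(c(0.2, 0.5, 1), te)$valid)    # positive slope
  expect_false(log_linear_fit(c(1, NA, 0.5), te)$valid)
  expect_false(log_linear_fit(c(1, 0.5), c(12, 24), exclude_first = TRUE)$valid)
})

test_that("voxelwise map agrees with per-voxel scalar fits", {
  set.seed(43)
  te <- seq(12, 120, by = 12)
  sig <- array(abs(rnorm(10 * 4 * 3 * 2, 500, 150)), dim = c(10, 4, 3, 2))
  sig[, 1, 1, 1] <- 800 * exp(-te / 60)
  sig[2, 2, 1, 1] <- -1  # invalid voxel
  img <- multi_echo_image(sig, te)
  map <- compute_t2_map(img, exclude_first = TRUE)
  for (i in 1:4) for (j in 1:3) for (k in 1:2) {
    ref <- log_linear_fit(sig[, i, j, k], te, exclude_first = TRUE)
    expect_equal(map$valid[i, j, k], ref$valid)
    if (ref$valid) {
      expect_equal(map$t2[i, j, k], ref$t2, tolerance = 1e-12)
      expect_equal(map$fit_r2[i, j, k], ref$r2, tolerance = 1e-10)
    }
  }
  expect_false(map$valid[2, 1, 1])
  # all-zero image: every voxel invalid
  z <- compute_t2_map(multi_echo_image(array(0, c(3, 2, 2, 2)), c(10, 20, 30)))
  expect_false(any(z$valid))
})

test_that("exclusion default follows echo-train length; 3-echo uses all echoes", {
  te3 <- c(9.1, 72, 136)
  t2 <- 90
  sig3 <- array(rep(700 * exp(-te3 / t2), 8), dim = c(3, 2, 2, 2))
  map3 <- compute_t2_map(multi_echo_image(sig3, te3))  # default: no exclusion
  expect_lt(max(abs(map3$t2 - t2)), 1e-9)
  # excluding from a 2-echo train leaves too few echoes
  expect_error(compute_t2_map(multi_echo_image(sig3[1:2, , , , drop = FALSE],
                                               te3[1:2]), exclude_first = TRUE),
               "fewer than 2")
})

test_that("recovery is exact across the physiological range for both presets", {
  for (preset in c("cpmg10", "tse3")) {
    ep <- echo_preset(preset)
    for (t2 in c(30, 80, 200)) {
      s <- 1000 * exp(-ep$echo_times / t2)
      f <- log_linear_fit(s, ep$echo_times, exclude_first = ep$exclude_first)
      expect_lt(abs(f$t2 - t2), 1e-6)
    }
  }
})

test_that("noise degrades T2 accuracy monotonically", {
  ph <- tiny_phantom()
  fld <- render_t2_field(truth_row(4.68, 0.112), ph, seed = 50)
  med_err <- sapply(c(5, 25, 60), function(nsd) {
    ph2 <- tiny_phantom(noise_model = "rician", noise_sd = nsd)
    map <- compute_t2_map(simulate_multi_echo(fld$t2, ph2, seed = 51))
    m <- fld$masks$hippocampus$left & map$valid
    median(abs(map$t2[m] - fld$t2[m]))
  })
  expect_true(all(diff(med_err) > 0))
})

test_that("sum of echoes equals brute-force voxel summation", {
  te <- c(10, 20)
  ones <- multi_echo_image(array(1, c(2, 2, 2, 2)), te)
  expect_true(all(sum_of_echoes(ones) == 2))
  set.seed(44)
  sig <- array(runif(3 * 24), dim = c(3, 4, 3, 2))
  img <- multi_echo_image(sig, c(5, 10, 15))
  soe <- sum_of_echoes(img)
  for (i in 1:4) for (j in 1:3) for (k in 1:2)
    expect_equal(soe[i, j, k], sum(sig[, i, j, k]))
})

test_that("mask union obeys set arithmetic", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, , 1] <- TRUE      # 8 voxels
  b <- array(FALSE, c(4, 4, 2)); b[3:4, , 1] <- TRUE      # 8 voxels, disjoint
  expect_equal(sum(combine_masks(list(a, b))), 16)
  expect_identical(combine_masks(list(a)), a)
  c2 <- array(FALSE, c(4, 4, 2)); c2[2:3, , 1] <- TRUE    # overlaps both
  expect_equal(sum(combine_masks(list(a, c2))),
               sum(a) + sum(c2) - sum(a & c2))
  expect_error(combine_masks(list(a, array(FALSE, c(3, 3, 2)))), "do not match")
  # integer 0/1 masks are accepted
  expect_equal(sum(combine_masks(list(array(1L, c(2, 2, 1))))), 4)
})

test_that("ROI extraction caps are boundary-inclusive and idempotent", {
  t2 <- array(NA_real_, c(5, 1, 1))
  t2[, 1, 1] <- c(25, 30, 100, 200, 250)
  map <- structure(list(t2 = t2, valid = array(TRUE, c(5, 1, 1)),
                        fit_r2 = array(1, c(5, 1, 1)), voxel_size = c(1, 1, 1)),
                   class = "t2_map")
  mask <- array(TRUE, c(5, 1, 1))
  s <- extract_roi_samples(map, mask)
  expect_equal(sort(s$values), c(30, 100, 200))
  expect_equal(s$n_excluded_low, 1)
  expect_equal(s$n_excluded_high, 1)
  expect_equal(length(s$values) + s$n_excluded_low + s$n_excluded_high +
                 s$n_invalid, sum(mask))

  # invalid voxels never leak into the sample
  map$valid[3, 1, 1] <- FALSE
  s2 <- extract_roi_samples(map, mask)
  expect_false(100 %in% s2$values)
  expect_equal(s2$n_invalid, 1)

  # idempotence: re-extracting the kept values changes nothing
  map3 <- structure(list(t2 = array(s$values, c(3, 1, 1)),
                         valid = array(TRUE, c(3, 1, 1)),
                         fit_r2 = array(1, c(3, 1, 1)), voxel_size = c(1, 1, 1)),
                    class = "t2_map")
  s3 <- extract_roi_samples(map3, array(TRUE, c(3, 1, 1)))
  expect_equal(sort(s3$values), sort(s$values))
  expect_equal(s3$n_excluded_low + s3$n_excluded_high, 0)

  expect_error(extract_roi_samples(map, array(FALSE, c(5, 1, 1))), "empty mask")
  expect_error(extract_roi_samples(map, array(TRUE, c(4, 1, 1))), "do not match")
})

test_that("ROI volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 1)); m[1:10, 1:10, 1] <- TRUE
  expect_equal(roi_volume(m, c(1, 1, 1)), 100)
  m2 <- array(FALSE, c(10, 1, 1)); m2[1:10, 1, 1] <- TRUE
  expect_equal(roi_volume(m2, c(0.34, 0.34, 1.7)), 1.9652)
  expect_equal(roi_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), 0)
})

test_that("NIfTI round-trips preserve images, masks and maps", {
  ph <- tiny_phantom(noise_model = "rician")
  fld <- render_t2_field(truth_row(), ph, seed = 52)
  img <- simulate_multi_echo(fld$t2, ph, seed = 53)
  d <- withr::local_tempdir()
  p <- file.path(d, "img.nii.gz")
  write_multi_echo(img, p)
  img2 <- read_multi_echo(p)
  expect_equal(img2$signal, img$signal, tolerance = 1e-6)
  expect_equal(img2$echo_times, img$echo_times)

  mp <- file.path(d, "mask.nii.gz")
  write_mask(fld$masks$hippocampus$left, mp)
  expect_identical(read_mask(mp), fld$masks$hippocampus$left)

  map <- compute_t2_map(img)
  tp <- file.path(d, "t2.nii.gz")
  write_t2_map(map, tp)
  map2 <- read_t2_map(tp)
  expect_equal(map2$valid, map$valid)
  expect_equal(map2$t2[map$valid], map$t2[map$valid], tolerance = 1e-5)
})
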
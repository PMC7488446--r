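## Synthetic cohorts and multi-echo phantoms.
##
## The generator encodes the statistical structure the downstream analysis
## assumes: subject-level regional T2 distributions are log-logistic with
## group offsets (MCI widens sigma; AD raises mu) and linear age trends;
## voxel signals decay mono-exponentially over the echo train and acquire
## magnitude (Rician) noise; follow-up cognition is linear in age, baseline
## cognition and the true heterogeneity.

.GROUPS <- c("HC", "MCI", "AD")

#' Region-level generative parameters
#'
#' Ground-truth parameters of one region's T2 distribution and volume.
#' Defaults describe the hippocampus: log-median 4.68 log-ms (about 108 ms)
#' and heterogeneity 0.113 at age 70 for controls, with MCI widening the
#' distribution (+0.02) and AD raising the midpoint; heterogeneity grows
#' by 0.001 per year of age. Volumes are in mm^3.
#'
#' @param mu0 control log-median at age 70 (log-ms).
#' @param sigma0 control heterogeneity at age 70 (dimensionless).
#' @param delta_mu,delta_sigma group offsets, named HC/MCI/AD.
#' @param slope_mu_age,slope_sigma_age per-year age slopes.
#' @param volume_mean,volume_sd volume distribution (mm^3).
#' @param delta_vol group volume offsets (mm^3).
#' @param slope_vol_age volume age slope (mm^3/year; sign configurable,
#'   default 0).
#' @return list of region parameters.
#' @export
region_params <- function(mu0 = 4.68, sigma0 = 0.113,
                          delta_mu = c(HC = 0, MCI = 0.005, AD = 0.03),
                          delta_sigma = c(HC = 0, MCI = 0.02, AD = 0.015),
                          slope_mu_age = 0, slope_sigma_age = 0.001,
                          volume_mean = 3200, volume_sd = 300,
                          delta_vol = c(HC = 0, MCI = -250, AD = -350),
                          slope_vol_age = 0) {
  list(mu0 = mu0, sigma0 = sigma0, delta_mu = delta_mu,
       delta_sigma = delta_sigma, slope_mu_age = slope_mu_age,
       slope_sigma_age = slope_sigma_age, volume_mean = volume_mean,
       volume_sd = volume_sd, delta_vol = delta_vol,
       slope_vol_age = slope_vol_age)
}

#' Cohort generative specification
#'
#' Defaults reproduce the demographic structure of the combined two-study
#' cohort the analysis targets: 97 controls, 49 MCI, 10 AD (156 subjects),
#' group ages 69.3 +/- 8.58, 72.2 +/- 9.03 and 77.9 +/- 9.94 years, two
#' studies (the AD group only in study 1), and sex ratios 46:51, 27:22 and
#' 2:8 (male:female).
#'
#' @param group_sizes named counts for HC, MCI, AD.
#' @param age_mean,age_sd per-group age distribution (years); ages are
#'   redrawn until inside [40, 100].
#' @param male_frac per-group fraction of males (assigned deterministically
#'   as round(frac * n)).
#' @param yoe_mean,yoe_sd per-group years of education.
#' @param study1_frac per-group fraction of subjects belonging to study 1
#'   (the rest are study 2).
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param regions named list of [region_params()]; default a single
#'   hippocampus region.
#' @param cognition list of cognition-model coefficients, see
#'   [simulate_cognition()].
#' @param seed integer root seed; every generator consumes a deterministic
#'   offset of it.
#' @return object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(group_sizes = c(HC = 97, MCI = 49, AD = 10),
                        age_mean = c(HC = 69.3, MCI = 72.2, AD = 77.9),
                        age_sd = c(HC = 8.58, MCI = 9.03, AD = 9.94),
                        male_frac = c(HC = 46 / 97, MCI = 27 / 49, AD = 2 / 10),
                        yoe_mean = c(HC = 15.8, MCI = 14.2, AD = 13.1),
                        yoe_sd = c(HC = 3.16, MCI = 2.81, AD = 2.60),
                        study1_frac = c(HC = 50 / 97, MCI = 30 / 49, AD = 1),
                        icv_mean = 1.5e6, icv_sd = 1.5e5,
                        regions = list(hippocampus = region_params()),
                        cognition = list(baseline_mean = c(HC = 0, MCI = -4.08, AD = -8.5),
                                         baseline_age_slope = -0.05,
                                         baseline_sd = 1.0,
                                         intercept = 0, beta_age = -0.03,
                                         beta_baseline = 0.7, beta_sigma = -30,
                                         error_sd = 1.0),
                        seed = 20200910L) {
  spec <- structure(
    list(group_sizes = group_sizes, age_mean = age_mean, age_sd = age_sd,
         male_frac = male_frac, yoe_mean = yoe_mean, yoe_sd = yoe_sd,
         study1_frac = study1_frac, icv_mean = icv_mean, icv_sd = icv_sd,
         regions = regions, cognition = cognition, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks group sizes, positivity of spread parameters, and that every
#' region's heterogeneity stays positive over the admissible age range
#' [40, 100] for every group.
#'
#' @param spec a \code{cohort_spec}.
#' @return the spec, invisibly; errors name the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  chk <- function(cond, field, msg)
    if (!cond) stop(sprintf("invalid cohort spec: field '%s' %s", field, msg),
                    call. = FALSE)
  g <- .GROUPS
  chk(all(g %in% names(spec$group_sizes)), "group_sizes",
      "must be named HC, MCI, AD")
  chk(all(spec$group_sizes >= 0), "group_sizes", "must be >= 0")
  chk(all(spec$age_sd > 0), "age_sd", "must be > 0")
  chk(all(spec$yoe_sd > 0), "yoe_sd", "must be > 0")
  chk(spec$icv_sd > 0, "icv_sd", "must be > 0")
  chk(all(spec$male_frac >= 0 & spec$male_frac <= 1), "male_frac",
      "must lie in [0, 1]")
  chk(all(spec$study1_frac >= 0 & spec$study1_frac <= 1), "study1_frac",
      "must lie in [0, 1]")
  for (rn in names(spec$regions)) {
    rp <- spec$regions[[rn]]
    chk(rp$sigma0 > 0, paste0("regions$", rn, "$sigma0"), "must be > 0")
    for (grp in g) {
      s_lo <- rp$sigma0 + rp$delta_sigma[[grp]] + rp$slope_sigma_age * (40 - 70)
      s_hi <- rp$sigma0 + rp$delta_sigma[[grp]] + rp$slope_sigma_age * (100 - 70)
      chk(min(s_lo, s_hi) > 0, paste0("regions$", rn, "$delta_sigma/slope_sigma_age"),
          sprintf("gives non-positive heterogeneity for %s over ages [40, 100]", grp))
    }
  }
  invisible(spec)
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  # redraw (not clip) outside the admissible range
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate the demographic cohort table
#'
#' One row per subject with study, group, sex, age (truncated normal on
#' [40, 100]), years of education and intracranial volume. Deterministic
#' given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns subject_id, study, group, sex, age, yoe,
#'   icv_mm3.
#' @export
generate_cohort_table <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  rows <- lapply(.GROUPS, function(grp) {
    n <- spec$group_sizes[[grp]]
    if (n == 0) return(NULL)
    n_male <- round(spec$male_frac[[grp]] * n)
    n_s1 <- round(spec$study1_frac[[grp]] * n)
    data.frame(
      group = grp,
      study = rep(c("study1", "study2"), c(n_s1, n - n_s1)),
      sex = rep(c("M", "F"), c(n_male, n - n_male)),
      age = .rnorm_trunc(n, spec$age_mean[[grp]], spec$age_sd[[grp]], 40, 100),
      yoe = .rnorm_trunc(n, spec$yoe_mean[[grp]], spec$yoe_sd[[grp]], 5, 30),
      icv_mm3 = stats::rnorm(n, spec$icv_mean, spec$icv_sd),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(group = character(), study = character(),
                      sex = character(), age = numeric(), yoe = numeric(),
                      icv_mm3 = numeric(), stringsAsFactors = FALSE)
  tab$group <- factor(tab$group, levels = .GROUPS)
  tab <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

#' True regional T2 parameters for one subject
#'
#' Deterministic linear model: mu = mu0 + delta_mu[group] +
#' slope_mu_age (age - 70), and analogously for sigma. Ages are centred at
#' 70 years so the baseline parameters describe a 70-year-old control.
#'
#' @param row one row of a cohort table (needs \code{group} and \code{age}).
#' @param spec the generating [cohort_spec()].
#' @return data.frame with one row per region: region, mu_true, sigma_true.
#' @export
sample_subject_t2_params <- function(row, spec) {
  grp <- as.character(row$group)
  out <- lapply(names(spec$regions), function(rn) {
    rp <- spec$regions[[rn]]
    mu <- rp$mu0 + rp$delta_mu[[grp]] + rp$slope_mu_age * (row$age - 70)
    sg <- rp$sigma0 + rp$delta_sigma[[grp]] + rp$slope_sigma_age * (row$age - 70)
    if (sg <= 0)
      stop(sprintf("parameterization error: sigma_true = %.4f <= 0 for region %s",
                   sg, rn))
    data.frame(region = rn, mu_true = mu, sigma_true = sg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ground truth for every subject and region
#'
#' Expands [sample_subject_t2_params()] over the cohort and adds true
#' volumes (normal noise around the region's age/group-adjusted mean).
#'
#' @param cohort table from [generate_cohort_table()].
#' @param spec the generating spec.
#' @return long data.frame: subject_id, group, age, region, mu_true,
#'   sigma_true, vol_true_mm3.
#' @export
cohort_truth <- function(cohort, spec) {
  set.seed(spec$seed + 1L)
  if (!nrow(cohort))
    return(data.frame(subject_id = character(), group = character(),
                      age = numeric(), region = character(),
                      mu_true = numeric(), sigma_true = numeric(),
                      vol_true_mm3 = numeric(), stringsAsFactors = FALSE))
  per <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    p <- sample_subject_t2_params(row, spec)
    p$subject_id <- row$subject_id
    p$group <- as.character(row$group)
    p$age <- row$age
    p
  })
  truth <- do.call(rbind, per)
  truth$vol_true_mm3 <- NA_real_
  for (rn in names(spec$regions)) {
    rp <- spec$regions[[rn]]
    idx <- truth$region == rn
    grp <- truth$group[idx]
    truth$vol_true_mm3[idx] <- rp$volume_mean +
      unlist(rp$delta_vol[grp]) +
      rp$slope_vol_age * (truth$age[idx] - 70) +
      stats::rnorm(sum(idx), 0, rp$volume_sd)
  }
  truth[, c("subject_id", "group", "age", "region", "mu_true", "sigma_true",
            "vol_true_mm3")]
}

#' Multi-echo phantom specification
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param voxel_size numeric 3-vector (mm); default the in-plane
#'   reconstructed resolution and slice thickness of the 10-echo protocol.
#' @param roi_geometry named list (per region) of left/right ellipsoids,
#'   each \code{list(center =, semiaxes =)} in voxel coordinates; NULL
#'   (default) places two disjoint hippocampus ellipsoids scaled to the
#'   grid.
#' @param echo_times echo times in ms, strictly increasing; default the
#'   10-echo CPMG train (12, 24, ..., 120 ms).
#' @param s0 proton-density signal scale (arbitrary units).
#' @param noise_sd per-channel noise SD in the same units as \code{s0}
#'   (signal-to-noise ratio = s0 / noise_sd).
#' @param noise_model one of \code{"rician"} (magnitude MRI, default),
#'   \code{"gaussian"}, \code{"none"}.
#' @param background_t2 T2 (ms) assigned to voxels outside every ROI.
#' @return object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 16L),
                         voxel_size = c(0.34, 0.34, 1.7),
                         roi_geometry = NULL,
                         echo_times = seq(12, 120, by = 12),
                         s0 = 1000, noise_sd = 20,
                         noise_model = c("rician", "gaussian", "none"),
                         background_t2 = 70) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (is.null(roi_geometry))
    roi_geometry <- default_roi_geometry(grid_shape)
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         roi_geometry = roi_geometry, echo_times = as.numeric(echo_times),
         s0 = s0, noise_sd = noise_sd, noise_model = noise_model,
         background_t2 = background_t2),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default left/right hippocampus ellipsoids scaled to a grid
#'
#' @param grid_shape integer 3-vector.
#' @return roi_geometry list with disjoint left/right ellipsoids.
#' @export
default_roi_geometry <- function(grid_shape) {
  list(hippocampus = list(
    left  = list(center = round(grid_shape * c(0.28, 0.5, 0.5)),
                 semiaxes = pmax(floor(grid_shape * c(0.17, 0.32, 0.32)), 1)),
    right = list(center = round(grid_shape * c(0.72, 0.5, 0.5)),
                 semiaxes = pmax(floor(grid_shape * c(0.17, 0.32, 0.32)), 1))))
}

#' @rdname phantom_spec
#' @param spec a \code{phantom_spec}.
#' @export
validate_phantom_spec <- function(spec) {
  te <- spec$echo_times
  if (length(te) < 1 || any(te <= 0) || any(diff(te) <= 0))
    stop("echo_times must be strictly increasing and > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 1))
    stop("grid_shape must be three positive integers")
  for (rn in names(spec$roi_geometry)) {
    for (h in names(spec$roi_geometry[[rn]])) {
      e <- spec$roi_geometry[[rn]][[h]]
      lo <- e$center - e$semiaxes
      hi <- e$center + e$semiaxes
      if (any(lo < 1) || any(hi > spec$grid_shape))
        stop(sprintf("ellipsoid %s/%s extends outside the grid", rn, h))
    }
  }
  masks <- lapply(names(spec$roi_geometry), function(rn)
    lapply(spec$roi_geometry[[rn]], function(e)
      ellipsoid_mask(spec$grid_shape, e$center, e$semiaxes)))
  flat <- unlist(masks, recursive = FALSE)
  if (length(flat) > 1) {
    tot <- Reduce(`+`, flat)
    if (any(tot > 1)) stop("ROI ellipsoids overlap; they must be disjoint")
  }
  invisible(spec)
}

#' Ellipsoid binary mask on a voxel grid
#'
#' @param grid_shape integer 3-vector.
#' @param center,semiaxes ellipsoid definition in voxel coordinates.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(grid_shape, center, semiaxes) {
  dx <- (seq_len(grid_shape[1]) - center[1]) / semiaxes[1]
  dy <- (seq_len(grid_shape[2]) - center[2]) / semiaxes[2]
  dz <- (seq_len(grid_shape[3]) - center[3]) / semiaxes[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(r2 <= 1, dim = grid_shape)
}

#' Draw log-logistic samples with physiological redraw bounds
#'
#' Inverse-CDF draws, redrawing any value outside \code{bounds} (clipping
#' would create point masses at the bounds).
#'
#' @param n number of draws.
#' @param mu,sigma log-logistic parameters.
#' @param bounds admissible interval in ms.
#' @return numeric vector of length n.
#' @export
rloglogis_bounded <- function(n, mu, sigma, bounds = c(1, 1000)) {
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  x <- rloglogis(n, mu, sigma)
  bad <- which(x < bounds[1] | x > bounds[2])
  while (length(bad)) {
    x[bad] <- rloglogis(length(bad), mu[bad], sigma[bad])
    bad <- bad[x[bad] < bounds[1] | x[bad] > bounds[2]]
  }
  x
}

#' Render a subject's true T2 field and ROI masks
#'
#' In-ROI voxels draw T2 from the subject's regional log-logistic
#' distribution (redrawing outside (1, 1000) ms); background voxels take a
#' fixed background T2.
#'
#' @param truth_params data.frame from [sample_subject_t2_params()] (one
#'   row per region).
#' @param phantom a [phantom_spec()].
#' @param seed integer seed.
#' @return list with \code{t2} (3D array, ms) and \code{masks} (per region,
#'   per hemisphere logical arrays).
#' @export
render_t2_field <- function(truth_params, phantom, seed) {
  validate_phantom_spec(phantom)
  set.seed(seed)
  t2 <- array(phantom$background_t2, dim = phantom$grid_shape)
  masks <- list()
  for (rn in names(phantom$roi_geometry)) {
    pr <- truth_params[truth_params$region == rn, , drop = FALSE]
    if (!nrow(pr))
      stop(sprintf("no truth parameters supplied for region '%s'", rn))
    masks[[rn]] <- list()
    for (h in names(phantom$roi_geometry[[rn]])) {
      e <- phantom$roi_geometry[[rn]][[h]]
      m <- ellipsoid_mask(phantom$grid_shape, e$center, e$semiaxes)
      nv <- sum(m)
      if (nv == 0)
        stop(sprintf("ROI %s/%s contains 0 voxels: cannot represent a distribution",
                     rn, h))
      t2[m] <- rloglogis_bounded(nv, pr$mu_true[1], pr$sigma_true[1])
      masks[[rn]][[h]] <- m
    }
  }
  list(t2 = t2, masks = masks)
}

#' Simulate a multi-echo acquisition of a T2 field
#'
#' Noiseless signal \eqn{S(TE) = s_0 e^{-TE/T_2}} per voxel; Rician noise
#' takes the magnitude of (S + n1, n2) with independent Gaussian channels,
#' Gaussian noise adds n1 only, and \code{"none"} returns the clean decay.
#'
#' @param t2_field 3D array of T2 (ms).
#' @param phantom a [phantom_spec()] (supplies echo times, s0, noise).
#' @param seed integer seed (ignored for noise_model "none").
#' @return a [multi_echo_image()].
#' @export
simulate_multi_echo <- function(t2_field, phantom, seed = 1L) {
  validate_phantom_spec(phantom)
  te <- phantom$echo_times
  dims <- dim(t2_field)
  ne <- length(te)
  sig <- array(0, dim = c(ne, dims))
  decay <- outer(te, as.vector(1 / t2_field))        # ne x nvox
  s <- phantom$s0 * exp(-decay)
  if (phantom$noise_model != "none" && phantom$noise_sd > 0) {
    set.seed(seed)
    n1 <- stats::rnorm(length(s), 0, phantom$noise_sd)
    if (phantom$noise_model == "rician") {
      n2 <- stats::rnorm(length(s), 0, phantom$noise_sd)
      s <- sqrt((s + n1)^2 + n2^2)
    } else {
      s <- s + n1
    }
  }
  sig[] <- s
  multi_echo_image(sig, te, phantom$voxel_size)
}

#' Simulate baseline and follow-up cognition
#'
#' Baseline cognition is the group mean plus an age term and Gaussian
#' noise. Follow-up cognition follows the linear generating model
#' \deqn{FollowUp = \beta_0 + \beta_{age} Age + \beta_{BL} Baseline +
#'   \beta_\sigma \sigma_{true} + \epsilon,}
#' with the heterogeneity of the marker region entering through
#' \eqn{\beta_\sigma} (negative by default: wider T2 distributions predict
#' decline).
#'
#' @param cohort cohort table.
#' @param truth long truth table from [cohort_truth()].
#' @param coeffs coefficient list (see [cohort_spec()]); element
#'   \code{beta_sigma} multiplies raw sigma_true, so on the default sigma
#'   scale (about 0.02 between groups) beta_sigma = -30 moves follow-up by
#'   about -0.6 test units per group step.
#' @param seed integer seed.
#' @param marker_region region whose sigma_true drives decline (default the
#'   first region in truth).
#' @return cohort with columns cog_baseline, cog_followup appended; the
#'   coefficients used are attached as attribute \code{"cognition_coeffs"}.
#' @export
simulate_cognition <- function(cohort, truth, coeffs, seed = 1L,
                               marker_region = NULL) {
  if (is.null(marker_region)) marker_region <- truth$region[1]
  tr <- truth[truth$region == marker_region, ]
  if (!all(cohort$subject_id %in% tr$subject_id))
    stop("schema error: truth table lacks sigma_true for some subjects")
  sg <- tr$sigma_true[match(cohort$subject_id, tr$subject_id)]
  set.seed(seed)
  grp <- as.character(cohort$group)
  baseline <- unlist(coeffs$baseline_mean[grp]) +
    coeffs$baseline_age_slope * (cohort$age - 70) +
    stats::rnorm(nrow(cohort), 0, coeffs$baseline_sd)
  followup <- coeffs$intercept + coeffs$beta_age * cohort$age +
    coeffs$beta_baseline * baseline + coeffs$beta_sigma * sg +
    stats::rnorm(nrow(cohort), 0, coeffs$error_sd)
  cohort$cog_baseline <- baseline
  cohort$cog_followup <- followup
  attr(cohort, "cognition_coeffs") <- coeffs
  cohort
}

#' Simulate subject-level observed cohort metrics
#'
#' Fast path for statistical calibration studies: generates the cohort,
#' the regional ground truth, observed T2 metrics (truth plus independent
#' Gaussian subject-level dispersion), observed volumes, and cognition —
#' without rendering voxel images. Returns a wide table with one row per
#' subject, columns \code{T2mu_<region>}, \code{T2sigma_<region>},
#' \code{vol_<region>_mm3}.
#'
#' @param spec a [cohort_spec()].
#' @param subject_sd_mu,subject_sd_sigma SD of the observed metric around
#'   its group/age trend: biological between-subject heterogeneity plus
#'   estimation error. Defaults chosen so the age trend explains roughly
#'   a tenth of the heterogeneity variance in controls, as regional T2
#'   cohort data show.
#' @param seed overrides spec$seed when given.
#' @return wide data.frame (cohort columns + metrics + cognition), with the
#'   truth table attached as attribute \code{"truth"}.
#' @export
simulate_cohort_metrics <- function(spec, subject_sd_mu = 0.03,
                                    subject_sd_sigma = 0.023,
                                    seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  cohort <- generate_cohort_table(spec)
  truth <- cohort_truth(cohort, spec)
  cohort <- simulate_cognition(cohort, truth, spec$cognition,
                               seed = spec$seed + 2L)
  set.seed(spec$seed + 3L)
  for (rn in names(spec$regions)) {
    tr <- truth[truth$region == rn, ]
    i <- match(cohort$subject_id, tr$subject_id)
    n <- nrow(cohort)
    cohort[[paste0("T2mu_", rn)]] <- tr$mu_true[i] +
      stats::rnorm(n, 0, subject_sd_mu)
    cohort[[paste0("T2sigma_", rn)]] <- tr$sigma_true[i] +
      stats::rnorm(n, 0, subject_sd_sigma)
    cohort[[paste0("vol_", rn, "_mm3")]] <- tr$vol_true_mm3[i]
  }
  attr(cohort, "truth") <- truth
  cohort
}
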
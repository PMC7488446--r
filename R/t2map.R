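## Voxelwise T2 mapping from multi-echo series.
##
## The estimator is the standard log-space mono-exponential fit: regress
## log signal on echo time by unweighted least squares, T2 = -1/slope.
## Voxels with nonpositive signal at any used echo, a nonnegative slope,
## or fewer than two usable echoes are flagged invalid, never thrown.

#' Multi-echo image container
#'
#' @param signal 4D array indexed (echo, x, y, z), non-negative, arbitrary
#'   units.
#' @param echo_times echo times in ms, strictly increasing, one per echo.
#' @param voxel_size voxel dimensions (mm).
#' @return object of class \code{"multi_echo_image"}.
#' @export
multi_echo_image <- function(signal, echo_times, voxel_size = c(1, 1, 1)) {
  if (length(dim(signal)) != 4)
    stop("signal must be a 4D (echo, x, y, z) array")
  if (dim(signal)[1] != length(echo_times))
    stop("number of echoes must equal length(echo_times)")
  if (length(echo_times) < 2)
    stop("need at least 2 echoes")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing and > 0")
  structure(list(signal = signal, echo_times = as.numeric(echo_times),
                 voxel_size = voxel_size),
            class = "multi_echo_image")
}

#' @export
print.multi_echo_image <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<multi-echo image: %d echoes (TE %g..%g ms), grid %dx%dx%d, voxels %s mm>\n",
              d[1], min(x$echo_times), max(x$echo_times), d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Echo-train presets
#'
#' \code{"cpmg10"}: 10 echoes at 12 ms spacing (TE 12..120 ms), first echo
#' excluded from fitting by convention. \code{"tse3"}: 3 echoes at TE 9.1,
#' 72 and 136 ms, all used.
#'
#' @param name preset name.
#' @return list with \code{echo_times} (ms) and \code{exclude_first}.
#' @export
echo_preset <- function(name = c("cpmg10", "tse3")) {
  name <- match.arg(name)
  switch(name,
         cpmg10 = list(echo_times = seq(12, 120, by = 12), exclude_first = TRUE),
         tse3 = list(echo_times = c(9.1, 72, 136), exclude_first = FALSE))
}

#' Log-linear mono-exponential fit for one voxel series
#'
#' Unweighted OLS of log(signal) on echo time; T2 = -1/slope,
#' s0 = exp(intercept). With \code{exclude_first = TRUE} the first echo is
#' dropped before fitting (the convention for CPMG trains, whose first
#' echo has a different pathway weighting).
#'
#' @param signals per-echo signal values.
#' @param echo_times matching echo times (ms).
#' @param exclude_first drop the first echo before fitting.
#' @return list with \code{t2} (ms), \code{s0}, \code{r2}, \code{valid}.
#'   Invalid fits (nonpositive signal, nonnegative slope, < 2 usable
#'   echoes) return \code{valid = FALSE} with NA estimates.
#' @examples
#' te <- seq(24, 120, by = 12)
#' log_linear_fit(exp(-te / 80), te)$t2   # 80
#' @export
log_linear_fit <- function(signals, echo_times, exclude_first = FALSE) {
  if (length(signals) != length(echo_times))
    stop("signals and echo_times must have equal length")
  if (exclude_first) {
    signals <- signals[-1]
    echo_times <- echo_times[-1]
  }
  invalid <- list(t2 = NA_real_, s0 = NA_real_, r2 = NA_real_, valid = FALSE)
  if (length(signals) < 2 || any(!is.finite(signals)) || any(signals <= 0))
    return(invalid)
  y <- log(signals)
  tc <- echo_times - mean(echo_times)
  slope <- sum(tc * y) / sum(tc^2)
  if (!is.finite(slope) || slope >= 0) return(invalid)
  intercept <- mean(y) - slope * mean(echo_times)
  ss_res <- sum((y - intercept - slope * echo_times)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(t2 = -1 / slope, s0 = exp(intercept),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1, valid = TRUE)
}

#' Compute a voxelwise T2 map
#'
#' Applies the log-linear fit to every voxel series (vectorized across the
#' grid). Voxels failing the fitting contract are marked invalid and carry
#' NA.
#'
#' @param image a [multi_echo_image()].
#' @param exclude_first drop the first echo; default TRUE for trains of 10
#'   or more echoes (CPMG-like), FALSE otherwise (TSE-like).
#' @return object of class \code{"t2_map"}: list with \code{t2} (3D, ms),
#'   \code{valid} (3D logical), \code{fit_r2} (3D), \code{voxel_size}.
#' @export
compute_t2_map <- function(image, exclude_first = NULL) {
  stopifnot(inherits(image, "multi_echo_image"))
  te <- image$echo_times
  if (is.null(exclude_first)) exclude_first <- length(te) >= 10
  keep <- if (exclude_first) -1L else seq_along(te)
  te_u <- te[keep]
  if (length(te_u) < 2)
    stop("fewer than 2 echoes remain after first-echo exclusion")
  d <- dim(image$signal)
  nvox <- prod(d[-1])
  sig <- matrix(image$signal, nrow = d[1])[keep, , drop = FALSE]

  ok <- colSums(!is.finite(sig) | sig <= 0) == 0
  t2 <- rep(NA_real_, nvox)
  r2 <- rep(NA_real_, nvox)
  if (any(ok)) {
    y <- log(sig[, ok, drop = FALSE])
    tc <- te_u - mean(te_u)
    denom <- sum(tc^2)
    slope <- as.vector(crossprod(tc, y)) / denom
    ybar <- colMeans(y)
    intercept <- ybar - slope * mean(te_u)
    fitted <- outer(te_u, slope) + rep(intercept, each = length(te_u))
    ss_res <- colSums((y - fitted)^2)
    ss_tot <- colSums((y - rep(ybar, each = length(te_u)))^2)
    neg <- is.finite(slope) & slope < 0
    t2_ok <- ifelse(neg, -1 / slope, NA_real_)
    r2_ok <- ifelse(neg, ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1), NA_real_)
    t2[ok] <- t2_ok
    r2[ok] <- r2_ok
    ok[ok] <- neg
  }
  structure(list(t2 = array(t2, d[-1]), valid = array(ok, d[-1]),
                 fit_r2 = array(r2, d[-1]), voxel_size = image$voxel_size),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<T2 map: grid %s, %d/%d valid voxels, median T2 %.1f ms>\n",
              paste(dim(x$t2), collapse = "x"), sum(x$valid), length(x$valid),
              stats::median(x$t2[x$valid])))
  invisible(x)
}

#' Sum-of-echoes image
#'
#' Voxelwise sum of the signal across all echoes — the single structural
#' volume used for segmentation of a multi-echo acquisition.
#'
#' @param image a [multi_echo_image()].
#' @return 3D array.
#' @export
sum_of_echoes <- function(image) {
  stopifnot(inherits(image, "multi_echo_image"))
  d <- dim(image$signal)
  array(colSums(matrix(image$signal, nrow = d[1])), d[-1])
}

#' Combine binary masks by voxelwise union
#'
#' Used to merge subregion masks (e.g. hippocampal subfields) into one
#' region mask.
#'
#' @param masks list of logical/0-1 arrays on identical grids.
#' @return logical array, the union.
#' @export
combine_masks <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("mask grids do not match")
  out <- Reduce(`|`, lapply(masks, function(m) array(m != 0, dim(m))))
  out
}

#' Extract a capped ROI sample vector from a T2 map
#'
#' Returns the valid in-mask T2 values inside the physiological interval
#' \code{[lower_cap, upper_cap]} (values outside are excluded, not clipped;
#' boundary values are kept). Exclusion counts are reported so sample
#' accounting is exact: kept + excluded_low + excluded_high + invalid =
#' mask voxel count.
#'
#' @param map a [compute_t2_map()] result.
#' @param mask logical/0-1 array on the map's grid.
#' @param lower_cap,upper_cap physiological caps (ms); defaults 30 and 200.
#' @param region,hemisphere,subject_id optional labels.
#' @return object of class \code{"roi_samples"}: list with \code{values},
#'   \code{n_excluded_low}, \code{n_excluded_high}, \code{n_invalid}, and
#'   the labels.
#' @export
extract_roi_samples <- function(map, mask, lower_cap = 30, upper_cap = 200,
                                region = NA_character_,
                                hemisphere = NA_character_,
                                subject_id = NA_character_) {
  stopifnot(inherits(map, "t2_map"))
  if (!identical(dim(mask), dim(map$t2)))
    stop("mask and map grids do not match")
  if (lower_cap >= upper_cap) stop("lower_cap must be < upper_cap")
  m <- array(mask != 0, dim(mask))
  if (!any(m)) stop("empty mask: no voxels to extract")
  inmask_valid <- m & map$valid
  n_invalid <- sum(m) - sum(inmask_valid)
  v <- map$t2[inmask_valid]
  low <- v < lower_cap
  high <- v > upper_cap
  structure(list(values = v[!low & !high],
                 n_excluded_low = sum(low), n_excluded_high = sum(high),
                 n_invalid = n_invalid, lower_cap = lower_cap,
                 upper_cap = upper_cap, region = region,
                 hemisphere = hemisphere, subject_id = subject_id),
            class = "roi_samples")
}

#' @export
print.roi_samples <- function(x, ...) {
  cat(sprintf("<ROI samples: %s/%s, n = %d kept (low %d, high %d, invalid %d), caps [%g, %g] ms>\n",
              x$region, x$hemisphere, length(x$values), x$n_excluded_low,
              x$n_excluded_high, x$n_invalid, x$lower_cap, x$upper_cap))
  invisible(x)
}

#' ROI volume from a binary mask
#'
#' @param mask logical/0-1 array.
#' @param voxel_size voxel dimensions (mm).
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
roi_volume <- function(mask, voxel_size) {
  sum(mask != 0) * prod(voxel_size)
}
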
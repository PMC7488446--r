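## File interchange: NIfTI-1 volumes with YAML echo-time sidecars, CSV
## tables, JSON ground truth. Multi-echo arrays are stored (x, y, z, echo)
## on disk (NIfTI convention) and (echo, x, y, z) in memory.

#' Write / read a multi-echo image as NIfTI-1 plus YAML sidecar
#'
#' @param image a [multi_echo_image()].
#' @param path output NIfTI path (\code{.nii} or \code{.nii.gz}); the
#'   sidecar is written next to it with extension \code{.yaml}.
#' @return \code{write_multi_echo}: the path, invisibly;
#'   \code{read_multi_echo}: a \code{multi_echo_image}.
#' @export
write_multi_echo <- function(image, path) {
  stopifnot(inherits(image, "multi_echo_image"))
  arr <- aperm(image$signal, c(2, 3, 4, 1))
  nii <- RNifti::asNifti(arr, pixdim = c(image$voxel_size, 1))
  RNifti::writeNifti(nii, path)
  yaml::write_yaml(list(echo_times_ms = as.numeric(image$echo_times),
                        voxel_size_mm = as.numeric(image$voxel_size)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_multi_echo
#' @export
read_multi_echo <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  arr <- as.array(RNifti::readNifti(path))
  multi_echo_image(aperm(arr, c(4, 1, 2, 3)),
                   echo_times = meta$echo_times_ms,
                   voxel_size = meta$voxel_size_mm)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Write / read a binary mask as uint8 NIfTI-1
#'
#' @param mask logical/0-1 array.
#' @param path NIfTI path.
#' @param voxel_size voxel dimensions (mm).
#' @return the path / a logical array.
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  arr <- array(as.integer(mask != 0), dim(mask))
  nii <- RNifti::asNifti(arr, pixdim = voxel_size, datatype = "uint8")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(arr != 0, dim(arr))
}

#' Write / read a T2 map as float32 NIfTI-1 (invalid voxels stored as NaN)
#'
#' @param map a [compute_t2_map()] result.
#' @param path NIfTI path.
#' @return the path / a \code{t2_map}.
#' @export
write_t2_map <- function(map, path) {
  stopifnot(inherits(map, "t2_map"))
  t2 <- map$t2
  t2[!map$valid] <- NaN
  nii <- RNifti::asNifti(t2, pixdim = map$voxel_size, datatype = "float")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_t2_map
#' @export
read_t2_map <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  valid <- is.finite(arr) & arr > 0
  structure(list(t2 = ifelse(valid, arr, NA_real_), valid = valid,
                 fit_r2 = array(NA_real_, dim(arr)),
                 voxel_size = RNifti::pixdim(nii)[seq_len(3)]),
            class = "t2_map")
}

#' Append ROI samples to a long data.frame
#'
#' @param samples list of \code{roi_samples} objects.
#' @return data.frame (subject_id, region, hemisphere, t2_ms).
#' @export
roi_samples_table <- function(samples) {
  do.call(rbind, lapply(samples, function(s)
    data.frame(subject_id = s$subject_id, region = s$region,
               hemisphere = s$hemisphere, t2_ms = s$values,
               stringsAsFactors = FALSE)))
}
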
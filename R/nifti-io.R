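#' Read/write BOLD series and 3D maps as NIfTI-1
#'
#' Thin wrappers over RNifti. Geometry carried: voxel sizes (pixdim) and,
#' for 4D images, the TR in the 4th pixdim slot.
#'
#' @param bold a [bold_series()].
#' @param path output file (".nii" or ".nii.gz").
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "bold_series"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param space_tag label recorded on the returned series.
#' @export
read_bold_nifti <- function(path, space_tag = "unspecified") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_series(array(as.numeric(img), dim(img)), voxel_size_mm = pd[1:3],
              tr_s = if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1,
              space_tag = space_tag)
}

#' @rdname write_bold_nifti
#' @param map 3D array.
#' @param voxel_size_mm voxel dimensions in mm.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a motion trace in the SPM rp_*.txt dialect
#'
#' Six whitespace-separated columns: translations in mm, rotations in
#' radians, one row per volume.
#'
#' @param motion t x 6 numeric matrix.
#' @param path text file path.
#' @export
write_motion_trace <- function(motion, path) {
  utils::write.table(format(as.matrix(motion), scientific = TRUE, digits = 8),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stopf("motion file must have 6 columns, found %d", ncol(m))
  dimnames(m) <- list(NULL, c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad"))
  m
}
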
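#' CT volume container
#'
#' A `ct_volume` is a 3-D array of Hounsfield units (HU) together with per-axis
#' voxel spacing in millimetres. It is the common currency of all image
#' operations in the package. The array is indexed `[row, col, slice]`; axial
#' slices are the third margin.
#'
#' @param data numeric 3-D array of HU values.
#' @param spacing numeric length-3 vector of voxel spacing in mm
#'   (row, column, slice). All entries must be positive.
#' @return An object of class `ct_volume`: a list with elements `data` and
#'   `spacing`.
#' @examples
#' v <- ct_volume(array(40, dim = c(8, 8, 4)), spacing = c(0.25, 0.25, 0.625))
#' voxel_volume(v)   # mm^3
#' pixel_area(v)     # in-plane mm^2
#' @export
ct_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array of HU values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel dimensions in mm")
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname ct_volume
#' @param v a `ct_volume`.
#' @export
voxel_volume <- function(v) prod(v$spacing)

#' @rdname ct_volume
#' @export
pixel_area <- function(v) v$spacing[1] * v$spacing[2]

stopifnot_ct_volume <- function(v) {
  if (!inherits(v, "ct_volume")) stop("expected a `ct_volume` object")
  if (is.null(v$spacing) || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("volume is missing voxel spacing metadata; areas would be unitless")
  invisible(v)
}

check_roi <- function(v, roi) {
  if (!identical(dim(roi), dim(v$data)))
    stop("ROI mask shape does not match volume shape")
  roi <- array(as.logical(roi), dim = dim(v$data))
  if (anyNA(roi)) stop("ROI mask contains NA")
  roi
}

#' Read and write CT volumes as NIfTI
#'
#' HU values are stored as signed 16-bit integers with voxel spacing in the
#' NIfTI header (`pixdim`).
#'
#' @param v a `ct_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti_volume` returns `path` invisibly; `read_nifti_volume`
#'   returns a `ct_volume`.
#' @export
write_nifti_volume <- function(v, path) {
  stopifnot_ct_volume(v)
  img <- RNifti::asNifti(array(as.integer(round(v$data)), dim = dim(v$data)))
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[seq_len(3)])
}

# round half away from zero, the convention used for reported percentages
# (5/16 = 31.25% prints as 31.3)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a percentage
#'
#' Rounds half away from zero so that e.g. 5/16 prints as 31.3.
#'
#' @param p proportion in `[0, 1]` (or `NA`).
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
as_pct <- function(p, digits = 1) round_half_up(100 * p, digits)
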
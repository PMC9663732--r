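#' 3D scan volume
#'
#' A `bm_volume` wraps a 3D intensity array together with its voxel geometry.
#' The array is indexed `[row, col, slice]`; `slice_index` used throughout the
#' package is 0-based and increases along the third array axis. In-plane pixel
#' spacing is given as (row, col) millimetres and the through-plane spacing as
#' the slice thickness, matching axially reconstructed black-blood series
#' (clinically 512 x 512 at 0.45 x 0.45 mm with 3 mm slices).
#'
#' @param data numeric 3D array of intensities, `[row, col, slice]`.
#' @param pixel_size_mm length-2 numeric, (row, col) spacing in mm.
#' @param slice_thickness_mm scalar slice thickness in mm.
#' @param scan_id character scan identifier.
#' @return An object of class `bm_volume`.
#' @export
bm_volume <- function(data, pixel_size_mm = c(0.9, 0.9),
                      slice_thickness_mm = 3.0, scan_id = "scan") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (length(pixel_size_mm) != 2L || any(pixel_size_mm <= 0))
    stop("pixel_size_mm must be two positive spacings")
  if (length(slice_thickness_mm) != 1L || slice_thickness_mm <= 0)
    stop("slice_thickness_mm must be a positive scalar")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 scan_id = as.character(scan_id)),
            class = "bm_volume")
}

#' @export
print.bm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bm_volume '%s'> %d x %d x %d voxels, %.3g x %.3g mm pixels, %.3g mm slices\n",
              x$scan_id, d[1], d[2], d[3],
              x$pixel_size_mm[1], x$pixel_size_mm[2], x$slice_thickness_mm))
  invisible(x)
}

#' @export
dim.bm_volume <- function(x) dim(x$data)

#' Read a volume from a NIfTI-1 file
#'
#' Spacings are taken from the NIfTI pixdim; only 3D images are accepted.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param scan_id scan identifier; defaults to the file name without extension.
#' @return A [bm_volume].
#' @export
read_volume <- function(path, scan_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage attributes
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions", length(dim(arr))))
  pd <- RNifti::pixdim(img)
  if (is.null(scan_id))
    scan_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  bm_volume(arr, pixel_size_mm = pd[1:2], slice_thickness_mm = pd[3],
            scan_id = scan_id)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a [bm_volume].
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "bm_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- c(v$pixel_size_mm, v$slice_thickness_mm)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
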
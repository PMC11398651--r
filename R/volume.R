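#' CT image volumes and VOI masks
#'
#' An `image_volume` is a 3D array of Hounsfield units (rows x cols x slices;
#' the third axis is the slice/Z axis) together with the voxel spacing in mm.
#' A VOI mask is a logical array of the same dimensions.
#'
#' @param data Numeric 3D array of HU values (finite).
#' @param spacing Numeric length-3 voxel spacing in mm (row, col, slice), all
#'   positive.
#' @return An object of class `image_volume`.
#' @export
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
image_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("image_volume: 'data' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("image_volume: 'spacing' must be 3 positive values (mm)")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

as_volume_array <- function(vol) {
  if (inherits(vol, "image_volume")) vol$data else vol
}

vol_spacing <- function(vol) {
  if (inherits(vol, "image_volume")) vol$spacing else c(1, 1, 1)
}

check_mask <- function(vol, mask) {
  a <- as_volume_array(vol)
  if (!identical(dim(a), dim(mask)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ", paste(dim(a), collapse = "x"))
  if (!any(mask)) stop("mask is empty")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving the (row, col, slice) array layout
#' and voxel spacing. Masks are written as 0/1 volumes. A geometry mismatch
#' between a volume and its mask beyond 1e-3 mm is a hard error at read time.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol An [image_volume()] (or logical array for masks).
#' @param spacing Voxel spacing in mm used when writing.
#' @return `read_volume_nifti` returns an [image_volume()];
#'   `read_mask_nifti` a logical array with a `spacing` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  image_volume(a, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(vol, path) {
  vol <- if (inherits(vol, "image_volume")) vol else image_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  v <- read_volume_nifti(path)
  m <- v$data > 0.5
  attr(m, "spacing") <- v$spacing
  m
}

#' @rdname read_volume_nifti
#' @export
write_mask_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  m <- array(as.numeric(vol), dim = dim(vol))
  write_volume_nifti(image_volume(m, spacing = spacing), path)
}

check_geometry <- function(vol, mask, tol_mm = 1e-3) {
  check_mask(vol, mask)
  ms <- attr(mask, "spacing")
  if (!is.null(ms) && any(abs(ms - vol_spacing(vol)) > tol_mm))
    stop("volume/mask voxel spacing mismatch beyond ", tol_mm, " mm")
  invisible(TRUE)
}

#' Discretise in-mask intensities into fixed-width bins
#'
#' Gray-level discretisation used by every quantised-texture feature: a voxel
#' with intensity `h` receives label `floor((h - min_in_mask)/bin_width) + 1`,
#' with bin edges anchored at the in-mask minimum so that adding a constant
#' HU offset to the volume leaves all labels unchanged. The default bin
#' width is 25 HU.
#'
#' @inheritParams first_order_features
#' @param bin_width Bin width in HU (> 0), default 25.
#' @return A `quantized_volume`: list with `labels` (integer array, `NA`
#'   outside the mask), `n_levels`, `bin_width` and `min_hu`.
#' @export
#' @examples
#' v <- image_volume(array(c(0, 25, 51, 10), c(2, 2, 1)))
#' m <- array(TRUE, c(2, 2, 1))
#' discretize_intensities(v, m)$labels
discretize_intensities <- function(vol, mask, bin_width = 25) {
  check_mask(vol, mask)
  if (bin_width <= 0) stop("bin_width must be > 0")
  a <- as_volume_array(vol)
  x <- a[mask]
  mn <- min(x)
  labels <- array(NA_integer_, dim(a))
  labels[mask] <- as.integer(floor((a[mask] - mn) / bin_width)) + 1L
  structure(list(labels = labels, n_levels = max(labels, na.rm = TRUE),
                 bin_width = bin_width, min_hu = mn),
            class = "quantized_volume")
}
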
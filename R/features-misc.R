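# Edge frequency, fractal dimension and spatial correlation.

# In-plane gradient magnitude at unit voxel offset (central differences).
slice_gradient_mag <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  gr <- rbind(sl[2, ] - sl[1, ],
              (sl[3:nr, , drop = FALSE] - sl[1:(nr - 2), , drop = FALSE]) / 2,
              sl[nr, ] - sl[nr - 1, ])
  gc <- cbind(sl[, 2] - sl[, 1],
              (sl[, 3:nc, drop = FALSE] - sl[, 1:(nc - 2), drop = FALSE]) / 2,
              sl[, nc] - sl[, nc - 1])
  sqrt(gr^2 + gc^2)
}

# Box-counting dimension of a set of pixels (logical matrix).
box_counting_dimension <- function(px) {
  if (!any(px)) return(0)
  n <- max(dim(px))
  sizes <- 2^(0:floor(log2(n / 2)))
  sizes <- sizes[sizes >= 1 & sizes <= n / 2]
  if (length(sizes) < 2) return(0)
  w <- which(px, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind((w[, 1] - 1L) %/% s, (w[, 2] - 1L) %/% s)))
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 2) return(0)
  stats::coef(stats::lm(log(counts[keep]) ~ log(1 / sizes[keep])))[2]
}

# Lag-1 in-plane autocorrelation coefficient over in-mask neighbour pairs,
# pooled across slices and the two in-plane directions.
lag1_autocorrelation <- function(a, m) {
  xs <- list(); ys <- list()
  for (k in seq_len(dim(m)[3])) {
    msl <- m[, , k]
    if (!any(msl)) next
    sl <- a[, , k]
    nr <- nrow(sl); nc <- ncol(sl)
    okh <- msl[, -nc, drop = FALSE] & msl[, -1, drop = FALSE]
    if (any(okh)) {
      xs[[length(xs) + 1L]] <- sl[, -nc, drop = FALSE][okh]
      ys[[length(ys) + 1L]] <- sl[, -1, drop = FALSE][okh]
    }
    okv <- msl[-nr, , drop = FALSE] & msl[-1, , drop = FALSE]
    if (any(okv)) {
      xs[[length(xs) + 1L]] <- sl[-nr, , drop = FALSE][okv]
      ys[[length(ys) + 1L]] <- sl[-1, , drop = FALSE][okv]
    }
  }
  x <- unlist(xs); y <- unlist(ys)
  if (length(x) < 2) return(1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)  # constant = smooth
  stats::cor(x, y)
}

#' Edge frequency, fractal dimension and spatial correlation
#'
#' * Edge Frequency: mean in-plane gradient magnitude at unit voxel offset,
#'   over the whole VOI, its boundary shell, and its interior.
#' * Fractal Dimension: box-counting dimension of the VOI's in-plane
#'   boundary pixel set, averaged over slices. Masks smaller than 4 voxels
#'   per in-plane axis give the degenerate value 0 with a warning.
#' * Spatial Correlation: `4 x` the mean lag-1 in-plane autocorrelation
#'   coefficient over in-mask neighbour pairs; saturates at 4 for smooth
#'   images and is strictly lower for oscillating textures.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector of the 5 miscellaneous texture features.
#' @export
misc_texture_features <- function(vol, mask) {
  check_mask(vol, mask)
  a <- as_volume_array(vol)
  bb <- mask_bbox(mask, margin = 4L)
  a <- crop_bbox(a, bb); m <- crop_bbox(mask, bb)
  a[!m] <- mean(a[m])
  shell <- mask_boundary_shell(m)

  gvals <- list(whole = list(), boundary = list(), interior = list())
  fds <- numeric(0)
  ext <- apply(which(m, arr.ind = TRUE), 2, function(i) diff(range(i)) + 1L)
  for (k in seq_len(dim(m)[3])) {
    msl <- slice2d(m, k)
    if (!any(msl)) next
    g <- slice_gradient_mag(slice2d(a, k))
    bsl <- shell[, , k]
    gvals$whole[[length(gvals$whole) + 1L]] <- g[msl]
    if (any(bsl)) gvals$boundary[[length(gvals$boundary) + 1L]] <- g[bsl]
    if (any(msl & !bsl))
      gvals$interior[[length(gvals$interior) + 1L]] <- g[msl & !bsl]
    if (ext[1] >= 4 && ext[2] >= 4)
      fds <- c(fds, box_counting_dimension(boundary2d(msl)))
  }
  fd <- if (length(fds)) mean(fds) else {
    warning("fractal dimension: mask too small for box counting, set to 0")
    0
  }
  ef <- function(s) {
    v <- unlist(gvals[[s]])
    if (length(v)) mean(v) else 0
  }
  c("Edge Frequency" = ef("whole"),
    "Edge Frequency Boundary" = ef("boundary"),
    "Edge Frequency NoBoundary" = ef("interior"),
    "Fractal Dimension" = fd,
    "Spatial Correlation" = 4 * lag1_autocorrelation(a, m))
}
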
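# Sigmoid edge features: the HU profile along the outward normal at sampled
# boundary voxels is fitted with a 3-parameter logistic
#   f(t) = a + b / (1 + exp(-(t - c) / w)),
# t in voxel steps from -5 (inside) to +5 (outside). The fit is exact least
# squares: for each (c, w) on a fixed grid, the profiled (a, b) solve a 2x2
# linear system; the grid optimum is returned. Amplitude is reported as the
# inside-minus-outside edge height (-b), so a hyperdense lesion on a darker
# background has positive amplitude. Profiles deliberately sample
# peri-lesional voxels outside the VOI: the feature measures the lesion
# edge, which does not exist inside the mask alone.

sigmoid_ray_t <- seq(-5, 5, by = 1)

sigmoid_fit_grid <- local({
  cs <- seq(-3, 3, by = 0.5)
  ws <- c(0.5, 0.75, 1, 1.5, 2, 3)
  expand.grid(c = cs, w = ws)
})

# Least-squares logistic fit of one profile; returns c(a, b, c, w, sse).
fit_sigmoid_profile <- function(y, t = sigmoid_ray_t) {
  best <- NULL
  for (g in seq_len(nrow(sigmoid_fit_grid))) {
    cc <- sigmoid_fit_grid$c[g]; w <- sigmoid_fit_grid$w[g]
    s <- 1 / (1 + exp(-(t - cc) / w))
    n <- length(t)
    sx <- sum(s); sxx <- sum(s^2); sy <- sum(y); sxy <- sum(s * y)
    det <- n * sxx - sx^2
    if (det < 1e-12) next
    b <- (n * sxy - sx * sy) / det
    a <- (sy - b * sx) / n
    sse <- sum((y - a - b * s)^2)
    if (is.null(best) || sse < best[5])
      best <- c(a = a, b = b, c = cc, w = w, sse = sse)
  }
  best
}

# Bilinear sampling of matrix m at fractional (row, col) coordinates.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Sigmoid boundary-edge features
#'
#' Fits a logistic edge model to the HU profile along the outward surface
#' normal at sampled boundary voxels and reports the mean and standard
#' deviation of the fitted amplitude (edge height, inside minus outside),
#' offset (inside plateau level) and width over the sampled profiles.
#'
#' @inheritParams first_order_features
#' @param max_profiles Maximum number of boundary profiles sampled
#'   (deterministically, evenly spaced along the boundary); default 24.
#' @return Named numeric vector: Sigmoid Amplitude/Offset/Width Mean and Std.
#' @export
sigmoid_boundary_features <- function(vol, mask, max_profiles = 24L) {
  check_mask(vol, mask)
  a <- as_volume_array(vol)
  bb <- mask_bbox(mask, margin = 8L)
  a <- crop_bbox(a, bb); m <- crop_bbox(mask, bb)
  # collect candidate boundary voxels with their outward normals, then
  # subsample deterministically before the (comparatively costly) fits
  cand <- list()
  for (k in seq_len(dim(m)[3])) {
    msl <- slice2d(m, k)
    if (!any(msl)) next
    bnd <- which(boundary2d(msl), arr.ind = TRUE)
    if (!nrow(bnd)) next
    # outward normal from the gradient of the smoothed mask indicator
    sm <- conv2d_bank(msl + 0,
                      list(outer(gaussian_kernel_1d(2), gaussian_kernel_1d(2))))[[1]][, , 1]
    nr <- nrow(sm); nc <- ncol(sm)
    gr <- rbind(sm[2, ] - sm[1, ],
                (sm[3:nr, , drop = FALSE] - sm[1:(nr - 2), , drop = FALSE]) / 2,
                sm[nr, ] - sm[nr - 1, ])
    gc <- cbind(sm[, 2] - sm[, 1],
                (sm[, 3:nc, drop = FALSE] - sm[, 1:(nc - 2), drop = FALSE]) / 2,
                sm[, nc] - sm[, nc - 1])
    for (idx in seq_len(nrow(bnd))) {
      r <- bnd[idx, 1]; c <- bnd[idx, 2]
      nrm <- c(-gr[r, c], -gc[r, c])
      nn <- sqrt(sum(nrm^2))
      if (nn < 1e-9) next
      cand[[length(cand) + 1L]] <- c(k, r, c, nrm / nn)
    }
  }
  if (!length(cand)) stop("sigmoid_boundary_features: no usable boundary profile")
  if (length(cand) > max_profiles) {
    keep <- unique(round(seq(1, length(cand), length.out = max_profiles)))
    cand <- cand[keep]
  }
  params <- lapply(cand, function(v) {
    ys <- bilinear_sample(slice2d(a, v[1]), v[2] + sigmoid_ray_t * v[4],
                          v[3] + sigmoid_ray_t * v[5])
    fit_sigmoid_profile(ys)
  })
  params <- Filter(Negate(is.null), params)
  if (!length(params)) stop("sigmoid_boundary_features: all profile fits degenerate")
  P <- do.call(rbind, params)
  amp <- -P[, "b"]; off <- P[, "a"]; wid <- P[, "w"]
  sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
  c("Sigmoid Amplitude Mean" = mean(amp), "Sigmoid Amplitude Std" = sdv(amp),
    "Sigmoid Offset Mean" = mean(off), "Sigmoid Offset Std" = sdv(off),
    "Sigmoid Width Mean" = mean(wid), "Sigmoid Width Std" = sdv(wid))
}
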
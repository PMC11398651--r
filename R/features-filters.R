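# Filter-response features: Gabor, Laws, Laplacian-of-Gaussian and Haar
# wavelet (DWF) banks. All filters are 2D and applied per axial slice on the
# VOI bounding box; out-of-mask voxels are replaced by the in-mask mean
# before filtering so that every feature depends only on in-mask intensities
# (boundary effects are then mask-derived, not background-derived).
# Responses are pooled over slices ("Z") and summarised over three voxel
# sets: whole VOI, boundary shell, and interior ("NoBoundary").

gabor_kernel <- function(frequency, theta, sigma = 2) {
  r <- ceiling(3 * sigma)
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)   # column offsets
  y <- matrix(rep(-r:r, times = 2 * r + 1), 2 * r + 1)  # row offsets
  xr <- x * cos(theta) + y * sin(theta)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  phase <- 2 * pi * frequency * xr
  list(re = env * cos(phase), im = env * sin(phase))
}

laws_vectors <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
                     S5 = c(-1, 0, 2, 0, -1))
laws_pairs <- list(c("L5", "E5"), c("E5", "L5"), c("L5", "S5"),
                   c("S5", "L5"), c("E5", "E5"), c("S5", "S5"))

laws_kernel <- function(k) {
  pr <- laws_pairs[[k]]
  outer(laws_vectors[[pr[1]]], laws_vectors[[pr[2]]])
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
  y <- matrix(rep(-r:r, times = 2 * r + 1), 2 * r + 1)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  k <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)  # enforce zero DC response
}

# Undecimated Haar low-pass cascade: level-l filter is [1, 1] at dilation
# 2^(l-1), applied along rows then columns of each frame (unnormalised box
# sums, replicate boundary). Accepts a matrix or a 3D stack.
haar_lowpass_step <- function(m, dilation) {
  nr <- dim(m)[1]; nc <- dim(m)[2]
  ri <- pmin(seq_len(nr) + dilation, nr)
  ci <- pmin(seq_len(nc) + dilation, nc)
  if (length(dim(m)) == 3L) {
    m2 <- m + m[ri, , , drop = FALSE]
    m2 + m2[, ci, , drop = FALSE]
  } else {
    m2 <- m + m[ri, , drop = FALSE]
    m2 + m2[, ci, drop = FALSE]
  }
}

# Crop to the VOI bounding box and replace out-of-mask voxels by the
# in-mask mean; returns the stack plus the three voxel-set masks.
prepare_filter_crop <- function(vol, mask, min_slice = 5L) {
  check_mask(vol, mask)
  a <- as_volume_array(vol)
  bb <- mask_bbox(mask, margin = 12L)
  a <- crop_bbox(a, bb); m <- crop_bbox(mask, bb)
  if (dim(m)[1] < min_slice || dim(m)[2] < min_slice) {
    warning("filter features: in-plane extent smaller than the filter support")
    return(NULL)
  }
  a[!m] <- mean(a[m])
  list(stack = a, mask = m, shell = mask_boundary_shell(m))
}

pool_sets <- function(resp, crop) {
  list(whole = resp[crop$mask], boundary = resp[crop$shell],
       interior = resp[crop$mask & !crop$shell])
}

empty_sets <- list(whole = numeric(0), boundary = numeric(0), interior = numeric(0))

# Pools the responder's responses over the three voxel sets. The responder
# receives the whole cropped mean-filled 3D stack (filters run frame-wise).
filter_response_sets <- function(vol, mask, responder, min_slice = 5L) {
  crop <- prepare_filter_crop(vol, mask, min_slice)
  if (is.null(crop)) return(empty_sets)
  pool_sets(responder(crop$stack), crop)
}

set_suffix <- c(whole = "", boundary = " Boundary", interior = " NoBoundary")

#' Filter-bank response features
#'
#' Applies one of four 2D filter families per axial slice and summarises the
#' in-mask responses over the whole VOI, its boundary shell, and its
#' interior:
#' * `Gabor`: mean magnitude over a bank of 4 orientations x 2 spatial
#'   frequencies (0.1, 0.3 cycles/voxel, sigma 2 voxels); statistics sum,
#'   Max, Min, Mean, Median, Std per voxel set.
#' * `Laws`: six 5x5 texture-energy kernels (zero-DC combinations of the
#'   L5/E5/S5 vectors); mean signed response per voxel set.
#' * `LoG`: Laplacian-of-Gaussian at sigma 2 mm; Uniformity and Entropy of
#'   the 25-unit-binned response and MGI (mean gray-level intensity of the
#'   filtered image) per voxel set.
#' * `DWF`: undecimated Haar low-pass cascade; sum of absolute approximation
#'   coefficients at levels 1-3 (`L`, `LL`, `LLL`) per voxel set.
#'
#' @inheritParams first_order_features
#' @param family One of `"Gabor"`, `"Laws"`, `"LoG"`, `"DWF"`.
#' @return Named numeric vector (18 Gabor, 18 Laws, 9 LoG or 9 DWF values).
#' @export
filter_response_features <- function(vol, mask, family) {
  if (!family %in% c("Gabor", "Laws", "LoG", "DWF"))
    stop("unknown filter family '", family,
         "'; valid families: Gabor, Laws, LoG, DWF")
  switch(family,
         Gabor = gabor_features(vol, mask),
         Laws = laws_features(vol, mask),
         LoG = log_features(vol, mask),
         DWF = dwf_features(vol, mask))
}

gabor_features <- function(vol, mask) {
  kernels <- list()
  for (th in c(0, 45, 90, 135) * pi / 180)
    for (fr in c(0.1, 0.3))
      kernels[[length(kernels) + 1L]] <- gabor_kernel(fr, th)
  responder <- function(stack) {
    bank <- conv2d_bank(stack, unlist(lapply(kernels, function(k)
      list(k$re, k$im)), recursive = FALSE))
    acc <- array(0, dim(stack))
    for (i in seq_along(kernels))
      acc <- acc + sqrt(bank[[2 * i - 1]]^2 + bank[[2 * i]]^2)
    acc / length(kernels)
  }
  sets <- filter_response_sets(vol, mask, responder)
  out <- numeric(0)
  for (s in names(sets)) {
    x <- sets[[s]]
    vals <- if (length(x)) {
      c(sum(x), max(x), min(x), mean(x), stats::median(x),
        if (length(x) > 1) stats::sd(x) else 0)
    } else rep(0, 6)
    names(vals) <- paste0("Gabor ", c("sum", "Max", "Min", "Mean", "Median", "Std"),
                          " Z", set_suffix[[s]])
    out <- c(out, vals)
  }
  out
}

laws_features <- function(vol, mask) {
  crop <- prepare_filter_crop(vol, mask)
  responses <- if (is.null(crop)) rep(list(empty_sets), 6) else {
    bank <- conv2d_bank(crop$stack, lapply(1:6, laws_kernel))
    lapply(bank, pool_sets, crop = crop)
  }
  out <- numeric(0)
  for (s in c("whole", "boundary", "interior")) {
    for (k in 1:6) {
      x <- responses[[k]][[s]]
      out[paste0("Laws ", k, " Z", set_suffix[[s]])] <-
        if (length(x)) mean(x) else 0
    }
  }
  out
}

log_features <- function(vol, mask, sigma_mm = 2, bin_width = 25) {
  sp <- vol_spacing(vol)
  sigma_vox <- sigma_mm / mean(sp[1:2])
  kern <- log_kernel(sigma_vox)
  sets <- filter_response_sets(vol, mask,
                               function(stack) conv2d_bank(stack, list(kern))[[1]])
  out <- numeric(0)
  for (s in names(sets)) {
    x <- sets[[s]]
    if (length(x)) {
      lab <- floor((x - min(x)) / bin_width)
      p <- tabulate(lab + 1L)
      p <- p[p > 0] / length(x)
      out[paste0("LoG Z Uniformity", set_suffix[[s]])] <- sum(p^2)
      out[paste0("LoG Z Entropy", set_suffix[[s]])] <- -sum(p * log2(p))
      out[paste0("LoG Z MGI", set_suffix[[s]])] <- mean(x)
    } else {
      out[paste0("LoG Z Uniformity", set_suffix[[s]])] <- 0
      out[paste0("LoG Z Entropy", set_suffix[[s]])] <- 0
      out[paste0("LoG Z MGI", set_suffix[[s]])] <- 0
    }
  }
  out
}

dwf_features <- function(vol, mask) {
  levels <- c("L", "LL", "LLL")
  crop <- prepare_filter_crop(vol, mask)
  out <- numeric(0)
  resp <- if (!is.null(crop)) crop$stack
  for (lv in 1:3) {
    sets <- if (is.null(crop)) empty_sets else {
      resp <- haar_lowpass_step(resp, 2L^(lv - 1L))
      pool_sets(resp, crop)
    }
    for (s in names(sets)) {
      x <- sets[[s]]
      out[paste0("DWF Z ", levels[lv], set_suffix[[s]])] <-
        if (length(x)) sum(abs(x)) else 0
    }
  }
  out[unlist(lapply(c("", " Boundary", " NoBoundary"), function(sf)
    paste0("DWF Z ", levels, sf)))]
}
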
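# Internal numerical helpers shared by the phantom generator and the
# feature extractors. All operate on plain numeric matrices/arrays.

# Reflect-pad a matrix by (pr, pc) on each side.
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(pr, nr))), seq_len(nr), nr + 1 - seq_len(min(pr, nr)))
  if (pr > nr) ri <- c(rep(1L, pr - nr), ri, rep(nr, pr - nr))
  ci <- c(rev(seq_len(min(pc, nc))), seq_len(nc), nc + 1 - seq_len(min(pc, nc)))
  if (pc > nc) ci <- c(rep(1L, pc - nc), ci, rep(nc, pc - nc))
  m[ri, ci, drop = FALSE]
}

# 2D filtering with replicate boundary handling. Odd-sized kernels go
# through EBImage's FFT implementation; the direct shift-and-add path
# remains for even kernels and as the reference in tests.
conv2d_direct <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  pr2 <- kr - 1L - pr; pc2 <- kc - 1L - pc
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(c(seq_len(pr) - pr, seq_len(nr), nr + seq_len(pr2)), 1L), nr)
  ci <- pmin(pmax(c(seq_len(pc) - pc, seq_len(nc), nc + seq_len(pc2)), 1L), nc)
  mp <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * mp[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

# `m` may be a matrix or a 3D array (filtered frame-wise along dim 3).
conv2d <- function(m, kernel) {
  if (nrow(kernel) %% 2L == 1L && ncol(kernel) %% 2L == 1L &&
      dim(m)[1] >= nrow(kernel) && dim(m)[2] >= ncol(kernel)) {
    # filter2 flips the kernel (true convolution); pre-flip so conv2d is
    # the sliding-window correlation the direct path implements
    EBImage::filter2(m, kernel[rev(seq_len(nrow(kernel))),
                               rev(seq_len(ncol(kernel))), drop = FALSE],
                     boundary = "replicate")
  } else if (length(dim(m)) == 3L) {
    out <- m
    for (k in seq_len(dim(m)[3])) out[, , k] <- conv2d_direct(m[, , k], kernel)
    out
  } else {
    conv2d_direct(m, kernel)
  }
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array (per-axis 1D convolution,
# reflective boundaries). sigma is in voxels, one value per axis.
gauss_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(a)
  smooth_axis <- function(a, axis, k) {
    if (length(k) == 1L) return(a)
    r <- (length(k) - 1L) %/% 2L
    n <- dim(a)[axis]
    idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
    out <- array(0, dim(a))
    for (s in seq_along(k)) {
      shift <- s - 1L - r
      ii <- idx(shift)
      out <- out + k[s] * switch(axis,
        a[ii, , , drop = FALSE],
        a[, ii, , drop = FALSE],
        a[, , ii, drop = FALSE])
    }
    out
  }
  for (ax in 1:3) {
    if (d[ax] > 1L) a <- smooth_axis(a, ax, gaussian_kernel_1d(sigma[ax]))
  }
  a
}

# Apply a bank of 2D kernels to a 3D stack (frame-wise) sharing one forward
# FFT per frame: replicate-pad each frame by the largest kernel radius,
# multiply in the Fourier domain, crop back. Equivalent to conv2d (sliding
# correlation with replicate boundary) for every kernel in the bank.
conv2d_bank <- function(stack, kernels) {
  d <- dim(stack)
  if (length(d) == 2L) { stack <- array(stack, c(d, 1L)); d <- dim(stack) }
  rr <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  rc <- max(vapply(kernels, function(k) (ncol(k) - 1L) %/% 2L, 1L))
  nr <- d[1]; nc <- d[2]; P1 <- nr + 2L * rr; P2 <- nc + 2L * rc
  ri <- pmin(pmax(seq_len(P1) - rr, 1L), nr)
  ci <- pmin(pmax(seq_len(P2) - rc, 1L), nc)
  # kernel spectra (conjugate for correlation), kernel centred at origin
  Ks <- lapply(kernels, function(k) {
    kr <- (nrow(k) - 1L) %/% 2L; kc <- (ncol(k) - 1L) %/% 2L
    km <- matrix(0, P1, P2)
    ui <- ((-kr:kr) %% P1) + 1L
    uj <- ((-kc:kc) %% P2) + 1L
    km[ui, uj] <- k
    Conj(stats::fft(km))
  })
  out <- lapply(kernels, function(k) array(0, d))
  for (f in seq_len(d[3])) {
    Fm <- stats::fft(stack[ri, ci, f])
    for (b in seq_along(Ks)) {
      r <- Re(stats::fft(Fm * Ks[[b]], inverse = TRUE)) / (P1 * P2)
      out[[b]][, , f] <- r[rr + seq_len(nr), rc + seq_len(nc)]
    }
  }
  out
}

# Bounding box of a logical 3D array, optionally grown by `margin` voxels.
mask_bbox <- function(mask, margin = 0L) {
  stopifnot(any(mask))
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# Extract slice k of a 3D array as a matrix (never drops to a vector).
slice2d <- function(a, k) {
  array(a[, , k], dim(a)[1:2])
}

# 2D mask boundary: in-mask pixels with at least one 4-neighbour outside.
boundary2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  interior <- m
  interior[] <- m &
    rbind(FALSE, m[-nr, , drop = FALSE]) &
    rbind(m[-1, , drop = FALSE], FALSE) &
    cbind(FALSE, m[, -nc, drop = FALSE]) &
    cbind(m[, -1, drop = FALSE], FALSE)
  m & !interior
}

# Boundary shell of a 3D mask: mask minus its one-voxel in-plane (2D) erosion,
# computed slice-wise along the third axis.
mask_boundary_shell <- function(mask) {
  out <- array(FALSE, dim(mask))
  for (k in seq_len(dim(mask)[3])) {
    sl <- slice2d(mask, k)
    if (any(sl)) out[, , k] <- boundary2d(sl)
  }
  out
}

#' Derive a per-stage random seed from a root seed
#'
#' Every source of randomness in the pipeline is seeded from one root seed
#' via this hash so that stages are reproducible yet decorrelated: the child
#' seed mixes the root with arbitrary stage labels (strings or integers).
#' Arithmetic is in doubles (exact below 2^53) and the result stays below
#' 2^31, a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param ... Stage labels (coerced to character) mixed into the hash.
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "patient", 7)
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(max(h, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Allow data.table's `[` semantics inside this package without attaching it.
.datatable.aware <- TRUE
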
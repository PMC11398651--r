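# Haralick gray-level co-occurrence features.
#
# Convention: distance-1 offsets in the four in-plane directions (0, 45, 90,
# 135 degrees), symmetric accumulation, matrix normalised per direction;
# feature values are averaged over directions within a slice and then over
# slices (the "Z" aggregation). Degenerate single-level slices give the
# formula limits (Contrast 0, ASM 1, Correlation 1, MCC 1).

glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(1L, 0L), `135` = c(1L, 1L))

# Count co-occurring label pairs in slice L (NA outside mask) at offset (dr, dc).
glcm_count <- function(L, dr, dc, ng) {
  nr <- nrow(L); nc <- ncol(L)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) return(NULL)
  a <- L[r1, c1, drop = FALSE]
  b <- L[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  counts <- tabulate((i - 1L) * ng + j, nbins = ng * ng)
  P <- matrix(counts, ng, ng, byrow = TRUE)
  P + t(P)  # symmetric
}

glcm_feature_names <- c(
  "GLCM Contrast", "GLCM Correlation", "GLCM Sum Squares", "GLCM ASM",
  "GLCM Entropy", "GLCM Sum Entropy", "GLCM Diff Entropy", "GLCM Diff Variance",
  "GLCM IDM", "GLCM Homogeneity", "GLCM Cluster Tendency", "GLCM IMC1",
  "GLCM IMC2", "GLCM MCC", "GLCM Max Prob", "GLCM Sum Average",
  "GLCM Sum Variance", "GLCM Diff Average", "GLCM Autocorrelation",
  "GLCM Cluster Shade", "GLCM Cluster Prominence")

glcm_features_from_matrix <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  pos <- p > 0

  contrast <- sum((i - j)^2 * p)
  autocorr <- sum(i * j * p)
  correlation <- if (sx > 0 && sy > 0) (autocorr - mux * muy) / (sx * sy) else 1
  sum_squares <- sum((i - mux)^2 * p)
  asm <- sum(p^2)
  entropy <- -sum(p[pos] * log2(p[pos]))

  # p_{x+y} indexed k = 2..2*ng, p_{x-y} indexed k = 0..ng-1
  kxy <- as.vector(i + j); kdiff <- as.vector(abs(i - j))
  pxy <- vapply(2:(2 * ng), function(k) sum(p[kxy == k]), numeric(1))
  pdm <- vapply(0:(ng - 1), function(k) sum(p[kdiff == k]), numeric(1))
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  sum_avg <- sum(ks * pxy)
  sum_var <- sum((ks - sum_avg)^2 * pxy)
  sum_ent <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  diff_avg <- sum(kd * pdm)
  diff_var <- sum((kd - diff_avg)^2 * pdm)
  diff_ent <- -sum(pdm[pdm > 0] * log2(pdm[pdm > 0]))

  idm <- sum(p / (1 + (i - j)^2))
  homog <- sum(p / (1 + abs(i - j)))
  ct <- sum((i + j - mux - muy)^2 * p)
  cs <- sum((i + j - mux - muy)^3 * p)
  cp <- sum((i + j - mux - muy)^4 * p)

  pxpy <- px[i] * py[j]
  ok <- pos & pxpy > 0
  hxy1 <- -sum(p[ok] * log2(pxpy[ok]))
  allp <- as.vector(px %o% py)
  hxy2 <- -sum(allp[allp > 0] * log2(allp[allp > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  occupied <- which(px > 0)
  mcc <- if (length(occupied) < 2) 1 else {
    ps <- p[occupied, occupied, drop = FALSE]
    pxs <- px[occupied]; pys <- py[occupied]
    Q <- (ps / pxs) %*% t(ps / pys)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }

  stats::setNames(c(contrast, correlation, sum_squares, asm, entropy, sum_ent,
                    diff_ent, diff_var, idm, homog, ct, imc1, imc2, mcc,
                    max(p), sum_avg, sum_var, diff_avg, autocorr, cs, cp),
                  glcm_feature_names)
}

#' Gray-level co-occurrence (Haralick) features
#'
#' Slice-wise symmetric GLCM at distance 1 over the four in-plane
#' directions; feature values are averaged over directions and slices.
#'
#' @param q A `quantized_volume` from [discretize_intensities()].
#' @param mask Logical VOI array matching the quantised volume.
#' @return Named numeric vector of the 21 GLCM features.
#' @export
glcm_features <- function(q, mask) {
  stopifnot(inherits(q, "quantized_volume"))
  ng <- q$n_levels
  acc <- NULL; nacc <- 0L
  for (k in seq_len(dim(mask)[3])) {
    if (!any(mask[, , k])) next
    L <- slice2d(q$labels, k)
    for (off in glcm_offsets) {
      P <- glcm_count(L, off[1], off[2], ng)
      if (is.null(P) || sum(P) == 0) next
      f <- glcm_features_from_matrix(P)
      acc <- if (is.null(acc)) f else acc + f
      nacc <- nacc + 1L
    }
  }
  if (nacc == 0L) stop("glcm_features: no slice contains a valid voxel pair")
  acc / nacc
}
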
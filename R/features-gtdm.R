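# Gray-tone difference matrix features (Amadasun & King), 3x3 in-plane
# neighbourhood. A voxel contributes if at least one of its 8 in-plane
# neighbours is inside the mask; the neighbourhood average excludes the
# centre voxel and out-of-mask neighbours. Features are computed per slice
# and averaged over slices.

gtdm_slice <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  inm <- !is.na(L)
  vals <- ifelse(inm, L, 0)
  nsum <- matrix(0, nr, nc); ncnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    nsum[r1, c1] <- nsum[r1, c1] + vals[r1 + dr, c1 + dc, drop = FALSE]
    ncnt[r1, c1] <- ncnt[r1, c1] + inm[r1 + dr, c1 + dc, drop = FALSE]
  }
  valid <- inm & ncnt > 0
  if (!any(valid)) return(NULL)
  A <- nsum[valid] / ncnt[valid]
  lev <- L[valid]
  s <- vapply(seq_len(ng), function(i) sum(abs(i - A[lev == i])), numeric(1))
  n_i <- tabulate(lev, nbins = ng)
  list(s = s, n = n_i, N = sum(n_i))
}

gtdm_features_from_matrix <- function(s, n_i, N) {
  ng <- length(s)
  p <- n_i / N
  lv <- seq_len(ng)
  occ <- which(p > 0)
  ngp <- length(occ)

  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 0

  contrast <- if (ngp >= 2) {
    grid <- expand.grid(i = occ, j = occ)
    sum(p[grid$i] * p[grid$j] * (grid$i - grid$j)^2) / (ngp * (ngp - 1)) *
      sum(s) / N
  } else 0

  busy_den <- 0; complexity <- 0; strength_num <- 0
  if (ngp >= 2) {
    for (i in occ) for (j in occ) {
      if (i == j) next
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
    }
  }
  busyness <- if (busy_den > 0) denom_coarse / busy_den else 0
  complexity <- complexity / N
  strength <- if (sum(s) > 0) strength_num / sum(s) else 0

  c("GTDM Strength" = strength, "GTDM Complexity" = complexity,
    "GTDM Coarseness" = coarseness, "GTDM Busyness" = busyness,
    "GTDM Contrast" = contrast)
}

#' Gray-tone difference matrix features
#'
#' Neighbourhood gray-tone difference features: Strength and Complexity
#' (the registry members) plus Coarseness, Busyness and Contrast, which are
#' computed alongside and exposed for testing.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of the 5 GTDM features.
#' @export
gtdm_features <- function(q, mask) {
  stopifnot(inherits(q, "quantized_volume"))
  acc <- NULL; nacc <- 0L
  for (k in seq_len(dim(mask)[3])) {
    if (!any(mask[, , k])) next
    m <- gtdm_slice(slice2d(q$labels, k), q$n_levels)
    if (is.null(m)) next
    f <- gtdm_features_from_matrix(m$s, m$n, m$N)
    acc <- if (is.null(acc)) f else acc + f
    nacc <- nacc + 1L
  }
  if (nacc == 0L) stop("gtdm_features: no voxel has an in-mask neighbour")
  acc / nacc
}
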
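# Gray-level run-length features (Galloway / Chu conventions).
#
# Runs are collected slice-wise along the requested in-plane directions; the
# run-length matrices of all directions are summed per slice, features are
# computed per slice and averaged over slices.

# Concatenate a slice's directed scan lines into one NA-separated vector
# (NA both marks out-of-mask gaps and breaks runs between lines).
rlm_scan_vector <- function(L, direction) {
  switch(direction,
    "0"   = as.vector(t(cbind(L, NA))),
    "90"  = as.vector(rbind(L, NA)),
    "45"  = unlist(lapply(split(L, row(L) + col(L)), c, NA), use.names = FALSE),
    "135" = unlist(lapply(split(L, row(L) - col(L)), c, NA), use.names = FALSE),
    stop("unknown run direction: ", direction))
}

# Run-length matrix R[level, length] for one slice over the given directions.
run_length_matrix <- function(L, ng, directions = c("0", "45", "90", "135")) {
  maxlen <- max(dim(L))
  R <- matrix(0, ng, maxlen)
  for (d in directions) {
    r <- rle(rlm_scan_vector(L, d))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    lv <- r$values[keep]; ln <- r$lengths[keep]
    cnt <- tabulate((ln - 1L) * ng + lv, nbins = ng * maxlen)
    R <- R + matrix(cnt, ng, maxlen)
  }
  R
}

run_length_feature_names <- c(
  "RSR Emphasis", "RLR Emphasis", "RGL Uniformity", "RPL Uniformity",
  "RHGLR Emphasis", "RLGLR Emphasis", "RSRLGL Emphasis", "RSRHGL Emphasis",
  "RLRHGL Emphasis", "RLRLGL Emphasis", "Run Percentage", "Run Entropy",
  "Run Length Variance", "Gray Level Variance")

rlm_features_from_matrix <- function(R, n_pixels, n_directions) {
  nr <- sum(R)
  if (nr == 0) stop("run_length: empty run-length matrix")
  i <- seq_len(nrow(R)); j <- seq_len(ncol(R))
  g <- rowSums(R); r <- colSums(R)
  II <- matrix(i, nrow(R), ncol(R))
  JJ <- matrix(j, nrow(R), ncol(R), byrow = TRUE)
  p <- R / nr
  mu_j <- sum(JJ * p); mu_i <- sum(II * p)
  pr <- p[p > 0]
  stats::setNames(c(
    sum(r / j^2) / nr,                 # short run emphasis
    sum(r * j^2) / nr,                 # long run emphasis
    sum(g^2) / nr,                     # gray-level nonuniformity
    sum(r^2) / nr,                     # run-length (primitive) nonuniformity
    sum(g * i^2) / nr,                 # high gray-level run emphasis
    sum(g / i^2) / nr,                 # low gray-level run emphasis
    sum(R / (II^2 * JJ^2)) / nr,       # short run low gray-level
    sum(R * II^2 / JJ^2) / nr,         # short run high gray-level
    sum(R * II^2 * JJ^2) / nr,         # long run high gray-level
    sum(R * JJ^2 / II^2) / nr,         # long run low gray-level
    nr / (n_pixels * n_directions),
    -sum(pr * log2(pr)),
    sum(p * (JJ - mu_j)^2),
    sum(p * (II - mu_i)^2)),
    run_length_feature_names)
}

#' Run-length texture features
#'
#' @inheritParams glcm_features
#' @param directions In-plane run directions (subset of `"0"`, `"45"`,
#'   `"90"`, `"135"`); default all four.
#' @return Named numeric vector of the 14 run-length features.
#' @export
run_length_features <- function(q, mask, directions = c("0", "45", "90", "135")) {
  stopifnot(inherits(q, "quantized_volume"))
  check_mask(q$labels, mask)
  acc <- NULL; nacc <- 0L
  for (k in seq_len(dim(mask)[3])) {
    msl <- mask[, , k]
    if (!any(msl)) next
    R <- run_length_matrix(slice2d(q$labels, k), q$n_levels, directions)
    f <- rlm_features_from_matrix(R, sum(msl), length(directions))
    acc <- if (is.null(acc)) f else acc + f
    nacc <- nacc + 1L
  }
  acc / nacc
}
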
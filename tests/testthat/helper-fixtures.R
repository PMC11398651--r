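# Shared fixtures, built in code. Heavier phantom cohorts are cached per
# session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# A small volume/mask pair with deterministic texture.
tiny_volume <- function(dims = c(12, 12, 3), seed = 42, spacing = c(1, 1, 1)) {
  set.seed(seed)
  v <- image_volume(array(stats::rnorm(prod(dims), 100, 20), dims), spacing)
  m <- array(FALSE, dims)
  m[3:(dims[1] - 2), 3:(dims[2] - 2), ] <- TRUE
  list(vol = v, mask = m)
}

# Desk-scale phantom spec used throughout the tests.
test_spec <- function(...) {
  args <- list(grid_shape = c(8, 64, 64), lesion_radii_mm = c(9, 9, 4))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

# Small cohort + full (2-observer, 16-sequence) feature table.
small_cohort_features <- function() {
  cache_fixture("small_cohort_features", {
    coh <- build_cohort(6, test_spec(), seed = 301)
    tbl <- extract_cohort_features(coh$cases)
    list(cohort = coh, tbl = tbl)
  })
}

# Independent brute-force GLCM: enumerate all co-occurring in-mask pairs of
# one slice at one offset, count symmetrically, normalise.
oracle_glcm <- function(L, dr, dc, ng) {
  P <- matrix(0, ng, ng)
  nr <- nrow(L); nc <- ncol(L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    i <- L[r, c]; j <- L[r2, c2]
    if (is.na(i) || is.na(j)) next
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  P
}

# Independent brute-force run enumerator for one scan line.
oracle_runs <- function(line) {
  runs <- list()
  cur <- NA; len <- 0
  for (v in c(line, NA)) {
    if (!is.na(v) && !is.na(cur) && v == cur) {
      len <- len + 1
    } else {
      if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
      cur <- v; len <- 1
    }
  }
  runs
}

oracle_rlm <- function(L, ng, directions = c("0", "45", "90", "135")) {
  maxlen <- max(dim(L))
  R <- matrix(0, ng, maxlen)
  lines <- list()
  for (d in directions) {
    ls <- switch(d,
      "0" = lapply(seq_len(nrow(L)), function(r) L[r, ]),
      "90" = lapply(seq_len(ncol(L)), function(c) L[, c]),
      "45" = split(L, row(L) + col(L)),
      "135" = split(L, row(L) - col(L)))
    lines <- c(lines, ls)
  }
  for (line in lines) {
    for (run in oracle_runs(as.vector(line)))
      R[run[1], run[2]] <- R[run[1], run[2]] + 1
  }
  R
}

# Independent GTDM (s-vector and level counts) for one slice.
oracle_gtdm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  s <- numeric(ng); n_i <- integer(ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(L[r, c])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(L[r2, c2]))
        nb <- c(nb, L[r2, c2])
    }
    if (!length(nb)) next
    i <- L[r, c]
    s[i] <- s[i] + abs(i - mean(nb))
    n_i[i] <- n_i[i] + 1L
  }
  list(s = s, n = n_i, N = sum(n_i))
}

# Independent CCC implementation (textbook formula, population moments).
oracle_ccc <- function(x, y) {
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Exhaustive two-sided rank-sum p-value by enumerating all group assignments.
perm_wilcoxon <- function(x, y) {
  all_v <- c(x, y); n1 <- length(x)
  combs <- utils::combn(length(all_v), n1)
  w_obs <- sum(rank(all_v)[seq_len(n1)])
  ws <- apply(combs, 2, function(i) sum(rank(all_v)[i]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Independent naive implementation of the correlated-feature removal rule.
oracle_prune <- function(values, threshold = 0.90) {
  keep <- colnames(values)
  repeat {
    if (length(keep) < 2) break
    rho <- suppressWarnings(stats::cor(values[, keep, drop = FALSE],
                                       method = "spearman"))
    rho[!is.finite(rho)] <- 0
    diag(rho) <- 0
    rho <- abs(rho)
    if (max(rho) <= threshold) break
    # find the maximal pair, first by magnitude then lexicographically
    best <- NULL
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      if (a >= b) next
      if (abs(rho[a, b] - max(rho)) < 1e-15) {
        cand <- sort(c(keep[a], keep[b]))
        if (is.null(best) || cand[1] < best[1] ||
            (cand[1] == best[1] && cand[2] < best[2])) best <- cand
      }
    }
    mean_abs <- sapply(keep, function(f) mean(rho[f, setdiff(keep, f)]))
    drop <- if (mean_abs[best[1]] > mean_abs[best[2]]) best[1]
            else if (mean_abs[best[2]] > mean_abs[best[1]]) best[2]
            else best[2]
    keep <- setdiff(keep, drop)
  }
  colnames(values)[colnames(values) %in% keep]
}
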
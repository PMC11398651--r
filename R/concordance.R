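#' Lin's concordance correlation coefficient
#'
#' Agreement statistic combining precision and accuracy:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population (1/n)
#' moments, as in Lin's original estimator. Degenerate limits: both vectors
#' constant and equal gives 1; both constant and different (or exactly one
#' constant) gives 0, the formula's limit.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, finite).
#' @return Concordance in `[-1, 1]`.
#' @export
#' @examples
#' lin_ccc(1:3, 2:4)  # 4/7
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("lin_ccc: x and y must have equal length")
  if (length(x) < 3) stop("lin_ccc: need at least 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("lin_ccc: values must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)  # both constant and equal
  2 * sxy / denom
}

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree perfectly
#' (returns 1 with a warning).
#'
#' @param a,b Logical arrays of identical shape.
#' @return Overlap fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice_coefficient: shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("dice_coefficient: both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Select the 16 analysis sequences per patient
#'
#' Applies the fixed sequence-selection rule: the first two NCE sequences,
#' and for each of L-AP and PVP the first two, the middle three and the last
#' two sequences (all seven when a phase has exactly seven). The middle
#' three are centred on `floor(n/2)` in 0-based indexing, i.e. 1-based
#' positions `m, m+1, m+2` with `m = floor(n/2)`.
#'
#' @param available Named list of per-phase sequence index vectors with
#'   elements `NCE`, `L-AP`, `PVP` (global, strictly increasing).
#' @return Named list (`NCE`, `L-AP`, `PVP`) of selected global indices;
#'   2 + 7 + 7 = 16 in total.
#' @export
#' @examples
#' select_phase_sequences(list("NCE" = 1:4, "L-AP" = 5:15, "PVP" = 16:24))
select_phase_sequences <- function(available) {
  need <- c("NCE" = 2L, "L-AP" = 7L, "PVP" = 7L)
  out <- list()
  for (ph in names(need)) {
    idx <- available[[ph]]
    n <- length(idx)
    if (is.null(idx) || n < need[[ph]])
      stop("select_phase_sequences: phase ", ph, " has ", n,
           " sequences; need >= ", need[[ph]])
    if (ph == "NCE") {
      sel <- idx[1:2]
    } else if (n == 7L) {
      sel <- idx
    } else {
      m <- floor(n / 2)                     # 0-based centre
      middle <- (m - 1L):(m + 1L) + 1L      # 1-based positions m, m+1, m+2
      sel <- idx[sort(unique(c(1L, 2L, middle, n - 1L, n)))]
    }
    out[[ph]] <- sel
  }
  stopifnot(length(unlist(out)) == 16L)
  out
}

# Reshape a long feature table into a [patient x sequence x feature] array
# for one radiologist. Errors if any (patient, sequence) cell is missing.
feature_cube <- function(tbl, radiologist, sequences) {
  t <- data.table::as.data.table(tbl)
  keep <- t$radiologist == radiologist & t$seq_index %in% sequences
  t <- t[keep, ]
  patients <- sort(unique(t$patient_id))
  feats <- sort(unique(t$feature))
  cube <- array(NA_real_, c(length(patients), length(sequences), length(feats)),
                dimnames = list(patients, as.character(sequences), feats))
  cube[cbind(match(t$patient_id, patients),
             match(t$seq_index, sequences),
             match(t$feature, feats))] <- t$value
  miss <- which(is.na(cube[, , 1, drop = FALSE]), arr.ind = TRUE)
  if (nrow(miss)) {
    bad <- unique(patients[miss[, 1]])
    stop("feature table missing sequences for patients: ",
         paste(bad, collapse = ", "))
  }
  cube
}

# CCC for each feature (columns) between two [patient x feature] matrices.
ccc_by_feature <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- colMeans(X^2) - mx^2; vy <- colMeans(Y^2) - my^2
  sxy <- colMeans(X * Y) - mx * my
  denom <- vx + vy + (mx - my)^2
  out <- ifelse(denom == 0, 1, 2 * sxy / denom)
  stats::setNames(out, colnames(X))
}

new_concordance_report <- function(ccc_mat, cutoff, comparison) {
  min_ccc <- apply(ccc_mat, 2, min)
  structure(list(ccc = ccc_mat, min_ccc = min_ccc,
                 reproducible = min_ccc >= cutoff,
                 cutoff = cutoff, comparison = comparison),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %s: %d/%d features reproducible (min CCC >= %.2f)\n",
              x$comparison, sum(x$reproducible), length(x$reproducible), x$cutoff))
  invisible(x)
}

#' Inter-observer feature reproducibility
#'
#' For each feature and each shared selected sequence of the given phase,
#' computes the CCC between the two radiologists' value vectors across
#' patients. A feature is reproducible when its CCC meets the cutoff for
#' every such sequence (`aggregate = "min"`, the strict default) or on
#' average (`aggregate = "mean"`, for sensitivity analysis).
#'
#' @param tbl Long feature table (columns patient_id, radiologist, phase,
#'   seq_index, feature, value) containing both radiologists.
#' @param phase One of `"NCE"`, `"L-AP"`, `"PVP"`, or `"all"` to pool every
#'   phase's selected sequences.
#' @param cutoff CCC reproducibility cutoff (default 0.90).
#' @param aggregate `"min"` or `"mean"` across per-sequence CCCs.
#' @return A `concordance_report`: per-feature CCC matrix (sequence x
#'   feature), min CCC, reproducible flags, cutoff.
#' @export
interobserver_reproducible <- function(tbl, phase = "all", cutoff = 0.90,
                                       aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  t <- data.table::as.data.table(tbl)
  if (phase != "all") {
    keep <- t$phase == phase
    t <- t[keep, ]
  }
  if (!nrow(t)) stop("interobserver_reproducible: no rows for phase ", phase)
  seqs <- sort(unique(t$seq_index))
  if (length(unique(t$patient_id)) < 3)
    stop("interobserver_reproducible: need >= 3 shared patients")
  c1 <- feature_cube(t, "R1", seqs)
  c2 <- feature_cube(t, "R2", seqs)
  stopifnot(identical(dimnames(c1), dimnames(c2)))
  ccc <- t(vapply(seq_along(seqs), function(s)
    ccc_by_feature(c1[, s, ], c2[, s, ]), numeric(dim(c1)[3])))
  rownames(ccc) <- as.character(seqs)
  rep_flag <- if (aggregate == "min") apply(ccc, 2, min) >= cutoff
              else colMeans(ccc) >= cutoff
  out <- new_concordance_report(ccc, cutoff,
                                sprintf("inter-observer R1 vs R2, phase %s", phase))
  out$reproducible <- rep_flag
  out
}

#' Pairwise inter-sequence reproducibility matrix
#'
#' For one radiologist, computes the per-feature CCC across patients for
#' every pair of the 16 selected sequences and counts, per pair, the
#' features meeting the cutoff. The diagonal holds the total feature count.
#'
#' @inheritParams interobserver_reproducible
#' @param radiologist `"R1"` or `"R2"`.
#' @return List with `counts` (symmetric 16 x 16 matrix of reproducible
#'   feature counts), `sequences`, `phases` and `ccc` (pair x feature
#'   matrix of CCCs, pairs named `"i-j"`).
#' @export
pairwise_sequence_matrix <- function(tbl, radiologist = "R1", cutoff = 0.90) {
  t <- data.table::as.data.table(tbl)
  keep <- t$radiologist == radiologist
  t <- t[keep, ]
  if (!nrow(t)) stop("pairwise_sequence_matrix: no rows for ", radiologist)
  if (length(unique(t$patient_id)) < 3)
    stop("pairwise_sequence_matrix: need >= 3 patients")
  seqs <- sort(unique(t$seq_index))
  cube <- feature_cube(t, radiologist, seqs)
  nf <- dim(cube)[3]; ns <- length(seqs)
  counts <- matrix(NA_real_, ns, ns, dimnames = list(seqs, seqs))
  diag(counts) <- nf
  pair_ccc <- list()
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ccc <- ccc_by_feature(cube[, i, ], cube[, j, ])
    counts[i, j] <- counts[j, i] <- sum(ccc >= cutoff)
    pair_ccc[[paste0(seqs[i], "-", seqs[j])]] <- ccc
  }
  phase_of <- t$phase[match(seqs, t$seq_index)]
  list(counts = counts, sequences = seqs, phases = phase_of,
       ccc = do.call(rbind, pair_ccc), cutoff = cutoff)
}

#' Intra-phase reproducible feature set
#'
#' Features whose CCC meets the cutoff for every within-phase pair of
#' selected sequences (1 pair for NCE, 21 pairs for L-AP / PVP).
#'
#' @inheritParams pairwise_sequence_matrix
#' @param phase `"NCE"`, `"L-AP"` or `"PVP"`.
#' @return Character vector of reproducible feature names (also attaches the
#'   per-pair CCC matrix as attribute `"ccc"`).
#' @export
intra_phase_reproducible <- function(tbl, radiologist = "R1", phase, cutoff = 0.90) {
  t <- data.table::as.data.table(tbl)
  keep <- t$phase == phase
  t <- t[keep, ]
  if (!nrow(t)) stop("intra_phase_reproducible: no rows for phase ", phase)
  pw <- pairwise_sequence_matrix(t, radiologist, cutoff)
  feats <- colnames(pw$ccc)
  ok <- apply(pw$ccc >= cutoff, 2, all)
  structure(feats[ok], ccc = pw$ccc)
}

#' Prune highly correlated features
#'
#' Iteratively removes one member of the most-correlated feature pair until
#' no pair of retained features has `|Spearman rho| >` the threshold. From
#' the offending pair, the member with the higher mean absolute Spearman
#' correlation against all currently retained features is dropped; ties are
#' broken lexicographically (the alphabetically later name is dropped).
#' Constant feature columns have undefined Spearman correlation and are
#' treated as correlation 0 with a warning.
#'
#' @param values Numeric matrix, patients in rows, features in (named)
#'   columns; >= 3 rows.
#' @param threshold Spearman threshold (default 0.90, strict inequality).
#' @return Character vector of retained feature names, in input order.
#' @export
prune_correlated <- function(values, threshold = 0.90) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (nrow(values) < 3) stop("prune_correlated: need >= 3 patients")
  const <- apply(values, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("prune_correlated: constant feature column(s) ",
            paste(colnames(values)[const], collapse = ", "),
            "; Spearman treated as 0")
  rho <- suppressWarnings(stats::cor(values, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  keep <- colnames(values)
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    if (length(keep) < 2 || max(sub) <= threshold) break
    mx <- max(sub)
    hits <- which(sub == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic pair choice: lexicographically first sorted (name1, name2)
    pn <- cbind(pmin(rownames(sub)[hits[, 1]], colnames(sub)[hits[, 2]]),
                pmax(rownames(sub)[hits[, 1]], colnames(sub)[hits[, 2]]))
    ord <- order(pn[, 1], pn[, 2])
    pair <- pn[ord[1], ]
    meanabs <- rowMeans(sub)  # vs all currently retained (incl. partner)
    drop <- if (meanabs[pair[1]] > meanabs[pair[2]]) pair[1]
            else if (meanabs[pair[2]] > meanabs[pair[1]]) pair[2]
            else max(pair)  # tie: drop the lexicographically later name
    keep <- setdiff(keep, drop)
  }
  colnames(values)[colnames(values) %in% keep]
}
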
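test_that("lin_ccc reproduces hand-evaluated values and limits", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  z <- c(-2, 0, 2, -1, 1)   # zero-mean
  expect_equal(lin_ccc(z, -z), -1)
  expect_equal(lin_ccc(c(2, 2, 2), c(2, 2, 2)), 1)   # equal constants
  expect_equal(lin_ccc(c(2, 2, 2), c(5, 5, 5)), 0)   # differing constants
  expect_error(lin_ccc(1:2, 1:2), "at least 3")
  expect_error(lin_ccc(1:4, 1:3), "equal length")
  expect_error(lin_ccc(c(1, 2, NA), 1:3), "finite")
})

test_that("lin_ccc agrees with an independent implementation and Lin's bound", {
  set.seed(11)
  for (rep in 1:500) {
    n <- sample(3:40, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.5, 5))
    y <- 0.5 * x + stats::rnorm(n, mean = stats::runif(1, -2, 2))
    ccc <- lin_ccc(x, y)
    expect_equal(ccc, oracle_ccc(x, y), tolerance = 1e-12)
    expect_lte(abs(ccc), abs(stats::cor(x, y)) + 1e-12)
    expect_gte(ccc, -1); expect_lte(ccc, 1)
  }
})

test_that("dice_coefficient counts overlaps and handles edge cases", {
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:2, 1:2, 1] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b[3:4, 3:4, 1] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  b[] <- FALSE; b[2:3, 1:2, 1] <- TRUE  # |A|=|B|=4, overlap 2
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(b, a), 0.5)  # symmetric
  expect_warning(d0 <- dice_coefficient(array(FALSE, c(2, 2, 1)),
                                        array(FALSE, c(2, 2, 1))), "empty")
  expect_equal(d0, 1)
  expect_error(dice_coefficient(a, array(TRUE, c(3, 3, 1))), "shape")
})

test_that("sequence selection applies the first-two/middle-three/last-two rule", {
  sel <- select_phase_sequences(list("NCE" = 1:5, "L-AP" = 6:16, "PVP" = 17:26))
  expect_equal(sel[["NCE"]], 1:2)
  expect_equal(sel[["L-AP"]], c(6, 7, 10, 11, 12, 15, 16))  # 1-based {1,2,5,6,7,10,11}
  expect_length(unlist(sel), 16L)
  sel7 <- select_phase_sequences(list("NCE" = 1:2, "L-AP" = 3:9, "PVP" = 10:16))
  expect_equal(sel7[["L-AP"]], 3:9)  # exactly 7: all selected
  expect_error(select_phase_sequences(list("NCE" = 1:2, "L-AP" = 3:8, "PVP" = 9:15)),
               "L-AP")
})

# Small synthetic feature table: linear patient effects so every feature is
# perfectly concordant, plus controllable noise columns.
synth_table <- function(n_pat = 8, features = c("fA", "fB", "fC"),
                        seqs = 1:4, phases = rep("NCE", 4), seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n_pat * length(features), 10, 4),
                 n_pat, length(features))
  rows <- list()
  for (p in seq_len(n_pat)) for (r in c("R1", "R2")) for (s in seq_along(seqs))
    rows[[length(rows) + 1]] <- data.table::data.table(
      patient_id = sprintf("P%02d", p), radiologist = r,
      phase = phases[s], seq_index = seqs[s],
      feature = features, value = base[p, ])
  data.table::rbindlist(rows)
}

test_that("identical observer tables are fully reproducible", {
  tbl <- synth_table()
  rep <- interobserver_reproducible(tbl, "NCE")
  expect_true(all(rep$reproducible))
  expect_true(all(rep$ccc >= 1 - 1e-12))
})

test_that("replacing one observer's feature with noise breaks its concordance", {
  tbl <- synth_table(n_pat = 39)
  set.seed(4)
  noisy <- tbl$radiologist == "R2" & tbl$feature == "fB"
  tbl$value[noisy] <- stats::rnorm(sum(noisy), 10, 4)
  rep <- interobserver_reproducible(tbl, "NCE")
  expect_false(rep$reproducible[["fB"]])
  expect_true(rep$reproducible[["fA"]])
  # order invariance: shuffling rows leaves the reproducible set unchanged
  rep2 <- interobserver_reproducible(tbl[sample(nrow(tbl)), ], "NCE")
  expect_identical(rep$reproducible[sort(names(rep$reproducible))],
                   rep2$reproducible[sort(names(rep2$reproducible))])
})

test_that("pairwise matrix is symmetric with the feature total on the diagonal", {
  tbl <- synth_table(seqs = 1:4, phases = c("NCE", "NCE", "PVP", "PVP"))
  pw <- pairwise_sequence_matrix(tbl, "R1")
  expect_true(isSymmetric(pw$counts))
  expect_equal(unname(diag(pw$counts)), rep(3, 4))
  expect_true(all(pw$counts[upper.tri(pw$counts)] == 3))  # identical sequences
})

test_that("intra-phase set equals the intersection over within-phase pairs", {
  tbl <- synth_table(n_pat = 12, seqs = 1:4, phases = rep("PVP", 4), seed = 8)
  # feature fC: constant in sequence 2, varying elsewhere -> excluded
  idx <- tbl$feature == "fC" & tbl$seq_index == 2
  tbl$value[idx] <- 5
  got <- intra_phase_reproducible(tbl, "R1", "PVP")
  expect_false("fC" %in% got)
  pw <- pairwise_sequence_matrix(tbl[tbl$phase == "PVP", ], "R1")
  manual <- colnames(pw$ccc)[apply(pw$ccc >= 0.9, 2, all)]
  expect_setequal(as.character(got), manual)
})

test_that("pruning collapses duplicates and leaves uncorrelated sets alone", {
  set.seed(2)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  m <- cbind(dup1 = a, dup2 = a + 1e-9 * stats::rnorm(20), indep = b)
  kept <- prune_correlated(m)
  expect_true("indep" %in% kept)
  expect_equal(sum(c("dup1", "dup2") %in% kept), 1L)
  m2 <- cbind(x = stats::rnorm(15), y = stats::rnorm(15))
  expect_identical(prune_correlated(m2), colnames(m2))
})

test_that("pruning matches the naive reference implementation", {
  set.seed(33)
  for (rep in 1:30) {
    n_feat <- sample(3:6, 1)
    n <- sample(6:12, 1)
    base <- matrix(stats::rnorm(n * n_feat), n, n_feat)
    # induce correlated pairs
    if (n_feat >= 2) base[, 2] <- base[, 1] + stats::rnorm(n, sd = 0.1)
    if (n_feat >= 4) base[, 4] <- -base[, 3] + stats::rnorm(n, sd = 0.05)
    colnames(base) <- paste0("f", seq_len(n_feat))
    expect_identical(prune_correlated(base, 0.9), oracle_prune(base, 0.9))
  }
})

test_that("retained sets never contain an over-threshold pair", {
  set.seed(44)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm(10 * 5), 10, 5)
    m[, 2] <- m[, 1] * 2 + stats::rnorm(10, sd = 0.01)
    colnames(m) <- paste0("f", 1:5)
    kept <- prune_correlated(m, 0.9)
    if (length(kept) >= 2) {
      rho <- abs(stats::cor(m[, kept], method = "spearman"))
      diag(rho) <- 0
      expect_lte(max(rho), 0.9)
    }
  }
})

test_that("constant feature columns prune with a warning, not an error", {
  m <- cbind(cst = rep(1, 10), ok = stats::rnorm(10))
  expect_warning(kept <- prune_correlated(m), "constant")
  expect_setequal(kept, c("cst", "ok"))
})
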
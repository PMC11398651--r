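test_that("wilcoxon test matches exact enumeration and rank invariance", {
  expect_equal(wilcoxon_grade_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2)), 0.1)
  expect_equal(wilcoxon_grade_test(rep(c(5, 5), 3), rep(c(1, 2), 3)), 1)
  x <- c(0.3, 1.2, 2.2, 5, 9, 14, 2.5)
  g <- c(1, 1, 1, 2, 2, 2, 1)
  expect_equal(wilcoxon_grade_test(x, g), wilcoxon_grade_test(exp(x), g))
  expect_error(wilcoxon_grade_test(1:3, c(1, 1, 1)), "2 groups")
})

test_that("exact path equals exhaustive permutation for all small splits", {
  set.seed(6)
  for (n1 in 2:4) for (n2 in 2:(10 - n1)) {
    if (n1 + n2 > 10) next
    x <- sample(100, n1); y <- sample(seq(101, 200), n2)  # tie-free
    expect_equal(wilcoxon_grade_test(c(x, y), rep(1:2, c(n1, n2))),
                 perm_wilcoxon(x, y), tolerance = 1e-12)
    x2 <- stats::rnorm(n1); y2 <- stats::rnorm(n2)
    expect_equal(wilcoxon_grade_test(c(x2, y2), rep(1:2, c(n1, n2))),
                 perm_wilcoxon(x2, y2), tolerance = 1e-12)
  }
})

test_that("train/test split is stratified, disjoint and deterministic", {
  grades <- rep(c(1, 2), c(7, 32))
  p <- split_train_test(grades, 29, 10, seed = 3)
  expect_length(p$train, 29); expect_length(p$test, 10)
  expect_length(intersect(p$train, p$test), 0)
  expect_setequal(c(p$train, p$test), 1:39)
  expect_true(all(table(grades[p$test]) >= 1))
  expect_true(all(table(grades[p$train]) >= 1))
  expect_identical(p, split_train_test(grades, 29, 10, seed = 3))
  expect_error(split_train_test(grades, 30, 10, seed = 1), "must equal")
})

test_that("SMOTE balances classes with convex synthetic minority points", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(10, 0, 1), 5, 2),
             matrix(stats::rnorm(40, 6, 1), 20, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), c(5, 20))
  out <- smote_oversample(X, y, seed = 2)
  expect_equal(as.integer(table(out$labels)), c(20L, 20L))
  expect_equal(out$features[1:25, ], X, ignore_attr = TRUE)  # originals preserved
  synth <- out$features[26:40, , drop = FALSE]
  minor <- X[1:5, , drop = FALSE]
  # each synthetic point lies on a segment between two minority rows
  for (i in seq_len(nrow(synth))) {
    ok <- FALSE
    for (a in 1:5) for (b in 1:5) {
      if (a == b) next
      d <- minor[b, ] - minor[a, ]
      t1 <- if (abs(d[1]) > 1e-12) (synth[i, 1] - minor[a, 1]) / d[1] else NA
      t2 <- if (abs(d[2]) > 1e-12) (synth[i, 2] - minor[a, 2]) / d[2] else NA
      ts <- stats::na.omit(c(t1, t2))
      if (length(ts) && all(abs(ts - mean(ts)) < 1e-9) &&
          mean(ts) >= -1e-9 && mean(ts) <= 1 + 1e-9) ok <- TRUE
    }
    expect_true(ok)
  }
  expect_identical(out, smote_oversample(X, y, seed = 2))
  # balanced input is a no-op
  bal <- smote_oversample(X[1:10, ], rep(c("a", "b"), each = 5), seed = 1)
  expect_identical(bal$features, X[1:10, ])
  expect_error(smote_oversample(X[1:6, ], rep(c("a", "b"), c(1, 5)), seed = 1),
               "minority")
})

test_that("RFE returns small candidate sets untouched and caps at 3", {
  X <- matrix(stats::rnorm(60), 30, 2); colnames(X) <- c("a", "b")
  y <- rep(c(0, 1), 15)
  expect_identical(rfe_select_features(X, y), c("a", "b"))
  X3 <- cbind(X, c2 = stats::rnorm(30))
  expect_identical(rfe_select_features(X3, y), c("a", "b", "c2"))
  expect_error(rfe_select_features(X, rep(1, 30)), "degenerate")
})

test_that("RFE finds a perfectly separating feature among noise", {
  set.seed(12)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * 10), n, 10)
  colnames(X) <- paste0("noise", 1:10)
  X[, 4] <- y * 4 + stats::rnorm(n, sd = 0.2)
  colnames(X)[4] <- "signal"
  sel <- rfe_select_features(X, y, seed = 5)
  expect_lte(length(sel), 3L)
  expect_true("signal" %in% sel)
})

test_that("confusion metrics follow the definitional arithmetic", {
  pred  <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)   # TP 3, FN 1, TN 5, FP 1
  m <- classification_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
})

test_that("a separable problem yields a perfect boosted-tree report", {
  set.seed(3)
  mk <- function(n) {
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(f1 = y * 3 + stats::rnorm(n, sd = 0.1),
               f2 = stats::rnorm(n))
    list(features = X, labels = y)
  }
  rep <- train_eval_boosted_trees(mk(40), mk(20), selected = c("f1", "f2"),
                                  seed = 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
})

test_that("label-randomised cohorts stay in the null AUC band", {
  set.seed(14)
  aucs <- replicate(20, {
    n <- 39
    y <- rep(c(0, 1), c(7, 32))[sample(39)]
    X <- matrix(stats::rnorm(n * 3), n, 3)
    colnames(X) <- paste0("f", 1:3)
    part <- split_train_test(y, 29, 10, seed = sample(1e6, 1))
    bal <- smote_oversample(X[part$train, ], y[part$train], seed = sample(1e6, 1))
    r <- train_eval_boosted_trees(bal,
      list(features = X[part$test, ], labels = y[part$test]),
      selected = colnames(X), seed = sample(1e6, 1))
    r$auc
  })
  expect_gte(mean(aucs), 0.25)
  expect_lte(mean(aucs), 0.75)
})

test_that("descriptive statistics table carries group moments and p-values", {
  set.seed(15)
  X <- cbind(f1 = c(stats::rnorm(7, 0), stats::rnorm(32, 3)),
             f2 = stats::rnorm(39))
  g <- rep(c(1, 2), c(7, 32))
  d <- grade_descriptive_stats(X, g)
  expect_equal(d$feature, c("f1", "f2"))
  expect_equal(d$group1_mean[1], mean(X[1:7, 1]))
  expect_equal(d$group2_sd[2], stats::sd(X[8:39, 2]))
  expect_lt(d$wilcoxon_p[1], 0.05)
  expect_gt(d$wilcoxon_p[2], 0.05)
})
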
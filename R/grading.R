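#' Wilcoxon rank-sum test between grade groups
#'
#' Two-sided rank-sum test of a feature between the two differentiation
#' groups: exact enumeration when the combined sample size is <= 10 and
#' there are no ties, otherwise the normal approximation with midrank ties
#' and continuity correction.
#'
#' @param values Numeric feature values, one per patient.
#' @param groups Binary group labels (two levels), same length.
#' @return Two-sided p-value.
#' @export
#' @examples
#' wilcoxon_grade_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2))  # 0.1
wilcoxon_grade_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("wilcoxon_grade_test: need exactly 2 groups")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (length(x) < 1 || length(y) < 1) stop("wilcoxon_grade_test: empty group")
  if (length(unique(c(x, y))) == 1L) return(1)  # no separation at all
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided",
    exact = (n <= 10) && !ties, correct = TRUE))
  p <- unname(res$p.value)
  if (is.nan(p)) 1 else p
}

#' Stratified train/test split
#'
#' Splits a cohort into training and test partitions stratified by grade
#' group (largest-remainder allocation of the test quota across groups),
#' deterministically for a given seed.
#'
#' @param grades Vector of binary grade labels, one per patient.
#' @param train_n,test_n Partition sizes; must sum to the cohort size.
#'   Defaults 29 / 10.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(grades, train_n = 29L, test_n = 10L, seed = 1L) {
  n <- length(grades)
  if (train_n + test_n != n)
    stop("split_train_test: train_n + test_n must equal cohort size ", n)
  g <- factor(grades)
  tab <- table(g)
  raw <- as.numeric(tab) * test_n / n
  quota <- floor(raw)
  rem <- test_n - sum(quota)
  if (rem > 0) {
    ord <- order(raw - quota, decreasing = TRUE)
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1
  }
  if (any(quota >= as.numeric(tab)))
    stop("split_train_test: stratification impossible (a group would vanish from training)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test_idx <- integer(0)
  for (k in seq_along(levels(g))) {
    idx <- which(g == levels(g)[k])
    test_idx <- c(test_idx, sort(sample(idx, quota[k])))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(grades[train_idx])) < 2 || length(unique(grades[test_idx])) < 2)
    stop("split_train_test: a grade group is absent from one partition")
  list(train = train_idx, test = test_idx)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by adding synthetic minority samples:
#' each synthetic row is a convex combination of a minority row and one of
#' its k nearest minority neighbours (Euclidean distance, k = 5 by default,
#' reduced to minority size - 1 when necessary). Originals are preserved;
#' an already balanced input is returned unchanged.
#'
#' @param features Numeric matrix (rows = samples, named columns).
#' @param labels Binary labels, one per row.
#' @param k Number of minority neighbours considered (default 5).
#' @param seed Integer seed.
#' @return List with balanced `features` matrix and `labels` vector.
#' @export
smote_oversample <- function(features, labels, k = 5L, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  g <- factor(labels)
  if (nlevels(g) != 2) stop("smote_oversample: need binary labels")
  tab <- table(g)
  if (tab[1] == tab[2]) return(list(features = features, labels = labels))
  minority <- levels(g)[which.min(tab)]
  min_idx <- which(g == minority)
  n_min <- length(min_idx)
  if (n_min < 2) stop("smote_oversample: minority class of 1 has no neighbour")
  k <- min(k, n_min - 1L)
  need <- abs(diff(as.numeric(tab)))

  X <- features[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- matrix(nn, nrow = k)  # k x n_min

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base <- sample(n_min, need, replace = TRUE)
  pick <- sample.int(k, need, replace = TRUE)
  gap <- stats::runif(need)
  synth <- X[base, , drop = FALSE] +
    gap * (X[nn[cbind(pick, base)], , drop = FALSE] - X[base, , drop = FALSE])
  rownames(synth) <- sprintf("synth%03d", seq_len(need))
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, need)))
}

#' Recursive feature elimination with bagged trees
#'
#' Selects at most `max_k` features: when the candidate set has `max_k` or
#' fewer members all are returned without elimination; otherwise recursive
#' feature elimination ranked by bagged-decision-tree importance under
#' 5-fold cross-validation (caret's `rfe` with treebag functions) returns
#' the best subset of size at most `max_k`.
#'
#' @param features Numeric matrix of candidate features (named columns).
#' @param labels Binary labels.
#' @param max_k Maximum number of selected features (default 3).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return Character vector of selected feature names (length <= max_k).
#' @export
rfe_select_features <- function(features, labels, max_k = 3L, folds = 5L, seed = 1L) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (length(unique(labels)) < 2) stop("rfe_select_features: degenerate labels")
  if (ncol(features) <= max_k) return(colnames(features))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  y <- factor(paste0("g", labels))
  # registry names contain spaces; give caret syntactic column names
  x <- as.data.frame(features)
  safe_names <- make.names(colnames(x), unique = TRUE)
  lookup <- stats::setNames(colnames(features), safe_names)
  colnames(x) <- safe_names
  ctrl <- caret::rfeControl(functions = caret::treebagFuncs,
                            method = "cv", number = folds, verbose = FALSE)
  fit <- tryCatch(
    caret::rfe(x = x, y = y, sizes = seq_len(max_k), rfeControl = ctrl),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # cross-validated elimination is infeasible on very small training sets
    # (folds can lose a class entirely); fall back to a single bagged-tree
    # importance ranking on the full training data
    warning("rfe_select_features: cross-validated RFE failed (",
            conditionMessage(fit), "); using bagged-importance ranking")
    imp <- bagged_importance(x, y, seed = seed)
    return(unname(lookup[names(utils::head(sort(imp, decreasing = TRUE), max_k))]))
  }
  # restrict to subset sizes <= max_k: take the best of those
  res <- fit$results[fit$results$Variables <= max_k, ]
  best_size <- res$Variables[which.max(res$Accuracy)]
  unname(lookup[utils::head(fit$optVariables, best_size)])
}

#' Train and evaluate the boosted-tree grade classifier
#'
#' Fits a gradient-boosted decision-tree classifier (XGBoost; fixed
#' documented hyperparameters: 300 trees, depth 3, learning rate 0.1) on
#' the balanced training set restricted to the selected features, and
#' evaluates on the held-out test set: rank-based AUC plus sensitivity,
#' specificity, NPV and PPV at the 0.5 probability threshold (grade group 2,
#' the higher grade, is the positive class).
#'
#' @param train List with `features` matrix and `labels` (e.g. from
#'   [smote_oversample()]).
#' @param test List with `features` matrix and `labels`.
#' @param selected Character vector of feature names to use.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta XGBoost hyperparameters.
#' @return A `model_report`: list with `selected`, `auc`, `sensitivity`,
#'   `specificity`, `npv`, `ppv`, `probabilities`, `split_sizes`, `seed`.
#' @export
train_eval_boosted_trees <- function(train, test, selected, seed = 1L,
                                     nrounds = 300L, max_depth = 3L, eta = 0.1) {
  if (!length(selected)) stop("train_eval_boosted_trees: no features selected")
  ytr <- as.integer(factor(train$labels)) - 1L
  yte <- as.integer(factor(test$labels, levels = levels(factor(train$labels)))) - 1L
  Xtr <- train$features[, selected, drop = FALSE]
  Xte <- test$features[, selected, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  booster <- xgboost::xgboost(
    x = Xtr, y = factor(ytr, levels = c(0, 1)), nrounds = nrounds,
    objective = "binary:logistic", max_depth = max_depth,
    learning_rate = eta, nthreads = 1, verbosity = 0)
  prob <- stats::predict(booster, Xte, type = "response")  # P(class 1)
  pred <- as.integer(prob >= 0.5)

  auc <- if (length(unique(yte)) < 2) {
    warning("train_eval_boosted_trees: single-class test set; AUC undefined")
    NA_real_
  } else rank_auc(prob, yte)
  m <- classification_metrics(pred, yte)
  structure(c(list(selected = selected, auc = auc), m,
              list(probabilities = prob, truth = yte,
                   split_sizes = c(train = nrow(Xtr), test = nrow(Xte)),
                   seed = seed)),
            class = "model_report")
}

#' Classification metrics from binary predictions
#'
#' Sensitivity, specificity, NPV and PPV from predicted and true binary
#' labels (1 = positive class). Undefined ratios (empty denominator)
#' are `NA`.
#'
#' @param pred,truth Binary vectors (0/1).
#' @return List with `sensitivity`, `specificity`, `npv`, `ppv`.
#' @export
#' @examples
#' # TP 3, FN 1, TN 5, FP 1
#' classification_metrics(c(1,1,1,0, 0,0,0,0,0,1), c(1,1,1,1, 0,0,0,0,0,0))
classification_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  divide <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = divide(tp, tp + fn),
       specificity = divide(tn, tn + fp),
       npv = divide(tn, tn + fn), ppv = divide(tp, tp + fp))
}

# Summed rpart importance over bootstrap resamples (bagged trees).
bagged_importance <- function(x, y, n_bags = 25L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  df <- cbind(x, .y = y)
  for (b in seq_len(n_bags)) {
    idx <- sample(nrow(df), replace = TRUE)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(minsplit = 2, cp = 0))
    vi <- fit$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
  }
  imp
}

# Rank-based AUC (Mann-Whitney statistic with midranks).
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> features: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("  AUC %.3f | sens %.2f | spec %.2f | NPV %.2f | PPV %.2f (n_train %d, n_test %d)\n",
              x$auc, x$sensitivity, x$specificity, x$npv, x$ppv,
              x$split_sizes["train"], x$split_sizes["test"]))
  invisible(x)
}

#' Per-feature descriptive statistics by grade group
#'
#' Replicates the descriptive layout of the clinical-correlation stage:
#' per feature, the mean and standard deviation in each grade group and the
#' two-sided Wilcoxon rank-sum p-value.
#'
#' @param features Numeric matrix (patients x named features).
#' @param grades Binary grade labels.
#' @return `data.table` with feature, group means/sds and `wilcoxon_p`.
#' @export
grade_descriptive_stats <- function(features, grades) {
  g <- factor(grades)
  stopifnot(nlevels(g) == 2)
  data.table::data.table(
    feature = colnames(features),
    group1_mean = apply(features[g == levels(g)[1], , drop = FALSE], 2, mean),
    group1_sd = apply(features[g == levels(g)[1], , drop = FALSE], 2, stats::sd),
    group2_mean = apply(features[g == levels(g)[2], , drop = FALSE], 2, mean),
    group2_sd = apply(features[g == levels(g)[2], , drop = FALSE], 2, stats::sd),
    wilcoxon_p = apply(features, 2, wilcoxon_grade_test, groups = grades))
}

#' Run the full grade-classification protocol
#'
#' The modeling chain applied to one (radiologist, phase) reproducible
#' feature set: stratified 29/10-style split, SMOTE balancing of the
#' training labels, treebag RFE (max 3 features, 5-fold CV) and an XGBoost
#' classifier evaluated on the held-out test set. SMOTE and RFE see only the
#' training partition.
#'
#' @param features Numeric matrix (patients x named features), already
#'   restricted to the reproducible set.
#' @param grades Binary grade labels, one per patient.
#' @param train_n,test_n Split sizes (default 74%/26% of the cohort when
#'   left `NULL`, i.e. 29/10 at n = 39).
#' @param seed Root seed; stage seeds (split, SMOTE, RFE, model) derive
#'   from it.
#' @return A `model_report` (see [train_eval_boosted_trees()]).
#' @export
classify_grades <- function(features, grades, train_n = NULL, test_n = NULL,
                            seed = 1L) {
  n <- length(grades)
  if (is.null(test_n)) test_n <- max(2L, round(0.26 * n))
  if (is.null(train_n)) train_n <- n - test_n
  part <- split_train_test(grades, train_n, test_n, seed = derive_seed(seed, "split"))
  tr_x <- features[part$train, , drop = FALSE]
  tr_y <- grades[part$train]
  bal <- smote_oversample(tr_x, tr_y, seed = derive_seed(seed, "smote"))
  sel <- rfe_select_features(bal$features, bal$labels,
                             seed = derive_seed(seed, "rfe"))
  train_eval_boosted_trees(
    bal, list(features = features[part$test, , drop = FALSE],
              labels = grades[part$test]),
    selected = sel, seed = derive_seed(seed, "xgb"))
}
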
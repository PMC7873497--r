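#' Gini diversity index of a set of class fractions
#'
#' `1 - sum(f(i)^2)`. Zero for a pure node; positive when several classes
#' reach the node.
#'
#' @param fractions Non-negative class fractions summing to 1.
#' @param tol Tolerance on the unit-sum check.
#' @return The impurity value in `[0, 1)`.
#' @export
gini_impurity <- function(fractions, tol = 1e-8) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > tol)
    stop("fractions must be >= 0 and sum to 1", call. = FALSE)
  1 - sum(fractions^2)
}

# Best (feature, threshold) split of the rows in `idx`, minimizing the
# count-weighted Gini impurity of the children by exhaustive search over
# midpoints of adjacent distinct sorted values. Ties break to the lower
# feature index, then the lower threshold.
best_split <- function(xm, y_int, idx, n_class, min_leaf) {
  n <- length(idx)
  best <- NULL
  for (j in seq_len(ncol(xm))) {
    v <- xm[idx, j]
    ord <- order(v)
    vs <- v[ord]
    ys <- y_int[idx][ord]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) next
    cum <- sapply(seq_len(n_class), function(cl) cumsum(ys == cl))
    cum <- matrix(cum, ncol = n_class)
    cand <- distinct[distinct >= min_leaf & (n - distinct) >= min_leaf]
    if (length(cand) == 0) next
    nL <- cand
    nR <- n - nL
    cL <- cum[cand, , drop = FALSE]
    cR <- matrix(cum[n, ], nrow = length(cand), ncol = n_class,
                 byrow = TRUE) - cL
    gL <- 1 - rowSums((cL / nL)^2)
    gR <- 1 - rowSums((cR / nR)^2)
    w <- (nL * gL + nR * gR) / n
    i <- which.min(w)
    if (is.null(best) || w[i] < best$impurity - 1e-12) {
      thr <- (vs[cand[i]] + vs[cand[i] + 1]) / 2
      best <- list(j = j, threshold = thr, impurity = w[i])
    }
  }
  best
}

grow_node <- function(xm, y_int, idx, levels, depth, max_depth, min_leaf,
                      counter, max_splits) {
  n_class <- length(levels)
  counts <- tabulate(y_int[idx], nbins = n_class)
  fractions <- setNames(counts / length(idx), levels)
  label <- levels[which.max(counts)]
  leaf <- function() list(leaf = TRUE, n = length(idx),
                          fractions = fractions, label = label)
  if (max(fractions) == 1) return(leaf())
  if (depth >= max_depth) return(leaf())
  if (length(idx) < 2 * min_leaf) return(leaf())
  if (counter$used >= max_splits) return(leaf())
  sp <- best_split(xm, y_int, idx, n_class, min_leaf)
  if (is.null(sp)) return(leaf())
  counter$used <- counter$used + 1L
  go_left <- xm[idx, sp$j] <= sp$threshold
  list(leaf = FALSE, n = length(idx), fractions = fractions, label = label,
       feature = colnames(xm)[sp$j], j = sp$j, threshold = sp$threshold,
       left = grow_node(xm, y_int, idx[go_left], levels, depth + 1,
                        max_depth, min_leaf, counter, max_splits),
       right = grow_node(xm, y_int, idx[!go_left], levels, depth + 1,
                         max_depth, min_leaf, counter, max_splits))
}

#' Grow a Gini decision tree
#'
#' Recursive binary splitting: at each node the (feature, threshold) pair
#' minimizing the count-weighted Gini impurity of the two children is
#' chosen by exhaustive search over midpoints of adjacent distinct sorted
#' feature values. Splitting stops at purity, at the depth/split limits, or
#' when no split leaves both children with `min_leaf` samples. Leaves carry
#' the majority class. Missing feature values are imputed with the
#' training-set median of the feature (the medians travel with the model
#' and are reused at prediction time).
#'
#' @param features Data frame or matrix of numeric features.
#' @param labels Factor (or coercible) of class labels.
#' @param max_depth Maximum tree depth (root = depth 0; default `Inf`).
#' @param max_splits Maximum number of internal nodes (default `Inf`).
#' @param min_leaf Minimum samples per leaf (default 1).
#' @return An object of class `emc_tree`.
#' @export
grow_tree <- function(features, labels, max_depth = Inf, max_splits = Inf,
                      min_leaf = 1) {
  xm <- as.matrix(as.data.frame(features))
  storage.mode(xm) <- "double"
  labels <- as.factor(labels)
  if (nrow(xm) < 2) stop("need at least 2 samples", call. = FALSE)
  if (ncol(xm) < 1) stop("need at least 1 feature", call. = FALSE)
  medians <- apply(xm, 2, function(v) median(v, na.rm = TRUE))
  for (j in seq_len(ncol(xm))) {
    nas <- is.na(xm[, j])
    if (any(nas)) xm[nas, j] <- medians[j]
  }
  counter <- new.env(parent = emptyenv())
  counter$used <- 0L
  root <- grow_node(xm, as.integer(labels), seq_len(nrow(xm)),
                    levels(labels), 0L, max_depth, min_leaf, counter,
                    max_splits)
  structure(list(root = root, levels = levels(labels), medians = medians,
                 n_splits = counter$used,
                 params = list(max_depth = max_depth,
                               max_splits = max_splits,
                               min_leaf = min_leaf)),
            class = "emc_tree")
}

#' @export
print.emc_tree <- function(x, ...) {
  cat(sprintf("<emc_tree> %d split(s), classes: %s\n", x$n_splits,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes with a grown tree
#'
#' @param object An [grow_tree()] model.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.emc_tree <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata))
  storage.mode(xm) <- "double"
  xm <- xm[, names(object$medians), drop = FALSE]
  for (j in seq_len(ncol(xm))) {
    nas <- is.na(xm[, j])
    if (any(nas)) xm[nas, j] <- object$medians[j]
  }
  classify_one <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$j] <= node$threshold) node$left else node$right
    node$label
  }
  out <- vapply(seq_len(nrow(xm)),
                function(i) classify_one(object$root, xm[i, ]), "")
  factor(out, levels = object$levels)
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Tune tree parameters by stratified 10-fold cross-validation
#'
#' Each parameter combination in the grid is scored by its mean
#' misclassification rate across the folds; the combination with the least
#' error is refitted on the full data. Folds are stratified by class and
#' seeded.
#'
#' @param features,labels As in [grow_tree()].
#' @param grid Data frame of candidate parameters with columns among
#'   `max_depth`, `max_splits`, `min_leaf`. Default: depth 1-6 crossed with
#'   min_leaf 1-5.
#' @param k Number of folds (default 10).
#' @param seed Optional seed for the fold partition.
#' @return A list with `best` (the winning grid row), `cv_error` (its mean
#'   fold error), `errors` (per-row mean errors) and `tree` (refit on all
#'   data).
#' @export
tune_tree_cv <- function(features, labels, grid = NULL, k = 10,
                         seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (is.null(grid))
    grid <- expand.grid(max_depth = 1:6, min_leaf = 1:5)
  if (!is.null(seed)) set.seed(seed)
  folds <- stratified_folds(labels, k)
  features <- as.data.frame(features)
  errors <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pars <- as.list(grid[g, , drop = FALSE])
    fold_err <- c()
    for (f in seq_len(k)) {
      test <- which(folds == f)
      if (length(test) == 0) next
      tr <- do.call(grow_tree, c(list(features[-test, , drop = FALSE],
                                      labels[-test]), pars))
      pred <- predict(tr, features[test, , drop = FALSE])
      fold_err <- c(fold_err, mean(pred != labels[test]))
    }
    errors[g] <- mean(fold_err)
  }
  best_i <- which.min(errors)
  best <- grid[best_i, , drop = FALSE]
  tree <- do.call(grow_tree, c(list(features, labels),
                               as.list(best)))
  list(best = best, cv_error = errors[best_i], errors = errors, tree = tree)
}

#' Leave-one-out evaluation of a tree configuration
#'
#' For every sample, a tree is grown on the remaining n-1 samples and the
#' held-out sample is predicted; predictions accumulate into a confusion
#' matrix.
#'
#' @param features,labels As in [grow_tree()].
#' @param max_depth,max_splits,min_leaf Tree parameters (e.g. the `best`
#'   row from [tune_tree_cv()]).
#' @return A `confusion_matrix` (rows = true class, columns = predicted).
#' @export
loocv_evaluate <- function(features, labels, max_depth = Inf,
                           max_splits = Inf, min_leaf = 1) {
  labels <- as.factor(labels)
  features <- as.data.frame(features)
  n <- length(labels)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (i in seq_len(n)) {
    tr <- grow_tree(features[-i, , drop = FALSE], labels[-i],
                    max_depth = max_depth, max_splits = max_splits,
                    min_leaf = min_leaf)
    pred[i] <- predict(tr, features[i, , drop = FALSE])
  }
  confusion_matrix(labels, pred)
}

#' Confusion matrix
#'
#' Either cross-tabulates true and predicted labels, or validates a
#' supplied counts matrix (rows = true class, columns = predicted class).
#'
#' @param truth True labels, or a square counts matrix with dimnames.
#' @param predicted Predicted labels (when `truth` is a label vector).
#' @param labels Optional class ordering.
#' @return A matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted = NULL, labels = NULL) {
  if (is.matrix(truth)) {
    m <- truth
    if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
    if (is.null(rownames(m)) && !is.null(labels))
      dimnames(m) <- list(labels, labels)
    if (is.null(rownames(m)))
      stop("counts matrix needs class labels", call. = FALSE)
    if (any(m < 0)) stop("counts must be >= 0", call. = FALSE)
  } else {
    if (is.null(labels))
      labels <- union(levels(as.factor(truth)),
                      levels(as.factor(predicted)))
    truth <- factor(truth, levels = labels)
    predicted <- factor(predicted, levels = labels)
    m <- unclass(table(truth, predicted))
    dimnames(m) <- list(labels, labels)
  }
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' One-vs-rest counts for one class of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @param class One of its class labels.
#' @return A list with `TP`, `FP`, `FN`, `TN` (summing to the matrix
#'   total).
#' @export
one_vs_rest_counts <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!class %in% rownames(cm))
    stop(sprintf("unknown class '%s'", class), call. = FALSE)
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(TP = unname(tp), FP = unname(fp), FN = unname(fn), TN = unname(tn))
}

#' Diagnostic metrics from one-vs-rest counts
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative predictive
#' values, each as a percentage. A zero denominator yields `NA` (metric
#' undefined).
#'
#' @param counts A [one_vs_rest_counts()] result.
#' @return A list with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
class_metrics <- function(counts) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, list(
    sensitivity = pct(TP, TP + FN),
    specificity = pct(TN, TN + FP),
    ppv = pct(TP, TP + FP),
    npv = pct(TN, TN + FN)))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return `100 * trace / total`, in percent.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Full evaluation report for a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return A list with the matrix, per-class counts and metrics, and the
#'   overall accuracy.
#' @export
evaluation_report <- function(cm) {
  classes <- rownames(cm)
  per_class <- lapply(classes, function(cl) {
    cnt <- one_vs_rest_counts(cm, cl)
    c(cnt, class_metrics(cnt))
  })
  names(per_class) <- classes
  list(confusion = cm, per_class = per_class,
       overall_accuracy = overall_accuracy(cm))
}

#' Published screening thresholds as a fixed partial rule
#'
#' Applies the two screening splits published for the method: a
#' displaced-mode vertical cosine similarity of 0.74 at the root (at or
#' below it, the participant screens as a patient) and, above it, a
#' smooth-mode positional-error-distribution adjusted R^2 of 0.99 (above
#' which the participant screens as healthy). Feature combinations falling
#' outside these two documented branches return `"indeterminate"`.
#'
#' @param features Named feature vector containing
#'   `cosine_similarity_vertical_displaced` and the smooth-mode PED
#'   adjusted R^2 of `ped_axis`.
#' @param ped_axis Axis of the PED adjusted R^2 split (default
#'   `"vertical"`).
#' @return `"patient"`, `"healthy"` or `"indeterminate"`.
#' @export
published_screening_rule <- function(features,
                                     ped_axis = c("vertical",
                                                  "horizontal")) {
  ped_axis <- match.arg(ped_axis)
  cs_name <- "cosine_similarity_vertical_displaced"
  r2_name <- paste0("ped_adj_r2_", ped_axis, "_smooth")
  for (nm in c(cs_name, r2_name))
    if (!nm %in% names(features) || !is.finite(features[[nm]]))
      stop(sprintf("required feature '%s' missing", nm), call. = FALSE)
  if (features[[cs_name]] <= 0.74) return("patient")
  if (features[[r2_name]] > 0.99) return("healthy")
  "indeterminate"
}
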
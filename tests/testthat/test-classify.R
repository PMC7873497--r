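test_that("Gini diversity index values", {
  expect_equal(gini_impurity(1), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(rep(1 / 3, 3)), 2 / 3)
  expect_error(gini_impurity(c(0.5, 0.6)), "sum to 1")
  expect_error(gini_impurity(c(-0.1, 1.1)), "sum to 1")
})

test_that("tree growth: purity, separability, XOR depth behaviour", {
  x1 <- data.frame(a = rnorm(10))
  t1 <- grow_tree(x1, rep("z", 10))
  expect_true(t1$root$leaf)
  expect_equal(t1$n_splits, 0)

  # 1-D perfectly separable -> a single split, perfect training accuracy
  x2 <- data.frame(a = c(1:5, 11:15))
  y2 <- rep(c("lo", "hi"), each = 5)
  t2 <- grow_tree(x2, y2)
  expect_equal(t2$n_splits, 1)
  expect_equal(t2$root$threshold, 8)
  expect_equal(as.character(predict(t2, x2)), y2)

  # XOR: depth 1 is chance, depth 2 is perfect
  xor_x <- data.frame(a = rep(c(0, 0, 1, 1), 6), b = rep(c(0, 1, 0, 1), 6))
  xor_y <- factor(ifelse(xor_x$a == xor_x$b, "same", "diff"))
  d1 <- grow_tree(xor_x, xor_y, max_depth = 1)
  expect_lte(mean(predict(d1, xor_x) == xor_y), 0.5)
  d2 <- grow_tree(xor_x, xor_y, max_depth = 2)
  expect_equal(mean(predict(d2, xor_x) == xor_y), 1)

  # identical rows with mixed labels: majority leaf, no error
  t3 <- grow_tree(data.frame(a = rep(1, 5)), c("p", "p", "p", "q", "q"))
  expect_true(t3$root$leaf)
  expect_equal(t3$root$label, "p")

  expect_error(grow_tree(data.frame(a = 1), "z"), "2 samples")
})

test_that("grow_tree matches the exhaustive-search oracle on small instances", {
  set.seed(10)
  same_tree <- function(a, b) {
    if (a$leaf != b$leaf) return(FALSE)
    if (a$leaf) return(a$label == b$label)
    a$j == b$j && isTRUE(all.equal(a$threshold, b$threshold)) &&
      same_tree(a$left, b$left) && same_tree(a$right, b$right)
  }
  for (i in 1:40) {
    n <- sample(4:8, 1)
    p <- sample(1:3, 1)
    x <- as.data.frame(matrix(round(rnorm(n * p), 1), nrow = n))
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("a", "b"), y[2])[1]
    fit <- grow_tree(x, y)
    orc <- oracle_tree(x, y)
    expect_true(same_tree(fit$root, orc),
                label = sprintf("instance %d matches oracle", i))
    expect_equal(as.character(predict(fit, x)), oracle_tree_predict(orc, x))
  }
})

test_that("weighted child impurity never exceeds the parent along any path", {
  set.seed(11)
  x <- as.data.frame(matrix(rnorm(60 * 4), nrow = 60))
  y <- sample(c("a", "b", "c"), 60, replace = TRUE)
  tr <- grow_tree(x, y)
  check <- function(node) {
    if (node$leaf) return(invisible(TRUE))
    g <- gini_impurity(node$fractions)
    gl <- gini_impurity(node$left$fractions)
    gr <- gini_impurity(node$right$fractions)
    w <- (node$left$n * gl + node$right$n * gr) / node$n
    expect_lte(w, g + 1e-12)
    check(node$left); check(node$right)
  }
  check(tr$root)
})

test_that("predictions agree with rpart on cleanly separable data", {
  set.seed(12)
  x <- data.frame(u = c(rnorm(30, -3), rnorm(30, 3)), v = rnorm(60))
  y <- factor(rep(c("neg", "pos"), each = 30))
  ours <- predict(grow_tree(x, y, max_depth = 3), x)
  rp <- rpart::rpart(y ~ ., data = cbind(x, y), method = "class",
                     parms = list(split = "gini"),
                     control = rpart::rpart.control(minsplit = 2, cp = 0))
  theirs <- predict(rp, x, type = "class")
  expect_equal(as.character(ours), as.character(theirs))
})

test_that("cross-validated tuning is seeded and finds separable structure", {
  set.seed(13)
  x <- data.frame(u = c(rnorm(20, -4), rnorm(20, 4)),
                  v = rnorm(40))
  y <- rep(c("a", "b"), each = 20)

  one <- tune_tree_cv(x, y, grid = data.frame(max_depth = 2), seed = 1)
  expect_equal(one$best$max_depth, 2)

  tuned <- tune_tree_cv(x, y, seed = 1)
  expect_equal(tuned$cv_error, 0)
  tuned2 <- tune_tree_cv(x, y, seed = 1)
  expect_identical(tuned$best, tuned2$best)
  expect_identical(tuned$errors, tuned2$errors)

  expect_error(tune_tree_cv(x[1:5, ], y[1:5], k = 10), "exceeds")
})

test_that("leave-one-out evaluation conserves class counts", {
  x <- data.frame(a = rep(1, 8))
  y <- rep("only", 8)
  cm <- loocv_evaluate(x, y)
  expect_equal(unname(diag(cm)), 8)

  set.seed(14)
  x2 <- data.frame(u = c(rnorm(12, -4), rnorm(12, 4)), v = rnorm(24))
  y2 <- rep(c("a", "b"), each = 12)
  cm2 <- loocv_evaluate(x2, y2, max_depth = 2)
  expect_equal(unname(rowSums(cm2)), c(12, 12))
  expect_gte(overall_accuracy(cm2), 90)
})

test_that("published screening thresholds route participants correctly", {
  f <- setNames(rep(0.5, 40), stp_feature_names())
  f["cosine_similarity_vertical_displaced"] <- 0.60
  expect_equal(published_screening_rule(f), "patient")

  f["cosine_similarity_vertical_displaced"] <- 0.90
  f["ped_adj_r2_vertical_smooth"] <- 0.999
  expect_equal(published_screening_rule(f), "healthy")

  f["ped_adj_r2_vertical_smooth"] <- 0.95
  expect_equal(published_screening_rule(f), "indeterminate")

  expect_equal(published_screening_rule(f, ped_axis = "horizontal"),
               "indeterminate")
  expect_error(published_screening_rule(f[1:5]), "missing")
})

test_that("one-vs-rest counts and metrics reproduce small identities", {
  cm <- confusion_matrix(diag(10, 3), labels = c("a", "b", "c"))
  cnt <- one_vs_rest_counts(cm, "a")
  expect_equal(cnt, list(TP = 10, FP = 0, FN = 0, TN = 20))
  met <- class_metrics(cnt)
  expect_equal(unlist(met), c(sensitivity = 100, specificity = 100,
                              ppv = 100, npv = 100))
  expect_equal(overall_accuracy(cm), 100)

  even <- confusion_matrix(matrix(c(5, 5, 5, 5), 2),
                           labels = c("x", "y"))
  expect_equal(overall_accuracy(even), 50)

  zeros <- class_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(zeros$ppv))
  expect_equal(zeros$sensitivity, 0)

  expect_error(one_vs_rest_counts(cm, "nope"), "unknown class")
  expect_error(confusion_matrix(matrix(1:6, 2)), "square")
})
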
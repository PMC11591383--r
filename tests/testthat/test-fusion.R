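# Metric formulas, the stratified split, early fusion bookkeeping, and
# the grid-searched SVM.

test_that("metric formulas reproduce hand-computed confusion counts", {
  m <- metrics_from_counts(tp = 2, tn = 6, fp = 1, fn = 1)
  expect_equal(m$accuracy, 100 * (2 + 6) / 10)
  expect_equal(m$recall, 100 * 2 / (2 + 1), tolerance = 1e-9)
  expect_equal(m$precision, 100 * 2 / (2 + 1), tolerance = 1e-9)
  expect_equal(m$f1,
               100 * 2 * (2 / 3) * (2 / 3) / (2 / 3 + 2 / 3),
               tolerance = 1e-9)
  m2 <- metrics_from_counts(tp = 3, tn = 50, fp = 2, fn = 5)
  expect_equal(unlist(m2, use.names = FALSE),
               100 * c(53 / 60, 3 / 8, 3 / 5,
                       2 * (3 / 5) * (3 / 8) / (3 / 5 + 3 / 8)),
               tolerance = 1e-9)
  w <- testthat::capture_warnings(z <- metrics_from_counts(0, 5, 0, 0))
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(unlist(z, use.names = FALSE), c(100, 0, 0, 0))
})

test_that("perfect predictions score 100 on every weighted metric", {
  y <- rep(c("foraging", "other", "rumination"), times = c(5, 3, 4))
  r <- evaluate(y, y)
  expect_equal(c(r$accuracy, r$recall, r$precision, r$f1),
               rep(100, 4))
})

test_that("collapsed predictions on a balanced set give 33.33% recall", {
  y <- rep(c("foraging", "other", "rumination"), each = 10)
  r <- suppressWarnings(evaluate(rep("foraging", 30), y))
  expect_equal(r$recall, 100 / 3, tolerance = 1e-9)
  expect_equal(r$accuracy, r$recall)
})

test_that("accuracy equals support-weighted recall on any full evaluation", {
  set.seed(61)
  classes <- c("foraging", "other", "rumination")
  for (i in 1:5) {
    y <- sample(classes, 60, replace = TRUE, prob = c(0.5, 0.2, 0.3))
    p <- sample(classes, 60, replace = TRUE)
    r <- suppressWarnings(evaluate(p, y))
    expect_equal(r$accuracy, r$recall, tolerance = 1e-9)
    expect_true(all(r$per_class$tp + r$per_class$tn + r$per_class$fp +
                      r$per_class$fn == 60))
  }
  expect_error(evaluate(c("a", "b"), c("a", "zzz"), classes = c("a", "b")),
               class = "foldear_bad_eval")
})

test_that("stratified split honors 80/20 with largest-remainder rounding", {
  y <- rep(c("foraging", "other", "rumination"), times = c(33, 33, 34))
  sp <- split_train_test(y, 0.2, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  tr_counts <- sort(as.vector(table(y[sp$train])))
  expect_equal(tr_counts, c(26, 27, 27))
  expect_identical(sp, split_train_test(y, 0.2, seed = 5))
  expect_false(identical(sp, split_train_test(y, 0.2, seed = 6)))
  expect_error(split_train_test(c("a", "b", "b"), 0.2, 1),
               class = "foldear_bad_split")
})

test_that("early fusion concatenates blocks with exact span bookkeeping", {
  set.seed(62)
  n <- 9
  blocks <- list(MEL_FC1 = matrix(rnorm(n * 128), n),
                 CQT_FC1 = matrix(rnorm(n * 128), n),
                 ACOUSTIC = matrix(rnorm(n * 31), n))
  fused <- early_fuse(blocks)
  expect_equal(dim(fused$values), c(9L, 287L))
  expect_equal(fused$blocks$name, c("MEL_FC1", "CQT_FC1", "ACOUSTIC"))
  for (b in seq_len(3)) {
    span <- fused$blocks$start[b]:fused$blocks$end[b]
    expect_identical(fused$values[, span], unname(blocks[[b]]))
  }
  single <- early_fuse(blocks[2])
  expect_identical(single$values, blocks[[2]])
  expect_error(early_fuse(list(a = matrix(1, 2), b = matrix(1, 3))),
               class = "foldear_bad_fuse")
  expect_error(early_fuse(list()), class = "foldear_bad_fuse")
})

test_that("grid search scans 6 points and nails separable blobs", {
  blobs <- make_blobs(n_per_class = 20, noise_dims = 2, sep = 8, seed = 63)
  X <- apply_standardizer(fit_standardizer(blobs$X), blobs$X)
  fit <- grid_search_svm(X, blobs$y, seed = 4)
  expect_equal(nrow(fit$cv_table), 6)
  expect_equal(max(fit$cv_table$mean_f1), 1)
  expect_true(fit$kernel %in% c("linear", "radial"))
  expect_true(fit$cost %in% c(0.1, 1, 10))
  expect_equal(fit$gamma, 1 / ncol(X))
  fit2 <- grid_search_svm(X, blobs$y, seed = 4)
  expect_identical(fit$cv_table, fit2$cv_table)
  expect_identical(c(fit$kernel, fit$cost), c(fit2$kernel, fit2$cost))
  fixed <- grid_search_svm(X, blobs$y, grid = NULL, seed = 4)
  expect_identical(c(fixed$kernel, fixed$cost), c("radial", "1"))
})

test_that("unknown fusion blocks are rejected by name", {
  expect_error(run_experiment(NULL, "MEL_FC3"),
               class = "foldear_bad_recipe")
})

test_that("a single-block recipe equals chaining the stages by hand", {
  corpus <- small_corpus(8, seed = 77)
  y <- vapply(corpus, `[[`, character(1), "label")
  ex <- run_experiment(corpus, "ACOUSTIC", seed = 5)
  # same stages, same derived seeds, assembled manually
  split <- split_train_test(y, 0.2, foldear:::child_seed(5, 1))
  A <- acoustic_feature_matrix(corpus)
  std_a <- fit_standardizer(A[split$train, , drop = FALSE])
  sel <- svm_rfecv(apply_standardizer(std_a, A[split$train, , drop = FALSE]),
                   y[split$train], folds = 5,
                   seed = foldear:::child_seed(5, 3))
  B <- A[, sel$selected_names, drop = FALSE]
  std <- fit_standardizer(B[split$train, , drop = FALSE])
  fit <- grid_search_svm(apply_standardizer(std, B[split$train, , drop = FALSE]),
                         y[split$train], seed = foldear:::child_seed(5, 2))
  pred <- as.character(predict(fit$model,
                               apply_standardizer(std, B[split$test, ,
                                                         drop = FALSE])))
  manual <- evaluate(pred, y[split$test], classes = sort(unique(y)))
  expect_identical(ex$report$confusion, manual$confusion)
  expect_equal(ex$report$f1, manual$f1)
  expect_identical(ex$svm$kernel, fit$kernel)
  expect_identical(ex$svm$cost, fit$cost)
  # predict() on the held-out segments reproduces the frozen pipeline
  expect_identical(predict(ex, corpus[split$test]), ex$predictions)
})
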
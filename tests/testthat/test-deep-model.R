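# SheepVGG-Lite: architecture arithmetic, training schedule, deep-feature
# taps, EigenCAM against a dense SVD oracle, and serialization.

test_that("parameter count matches the per-layer arithmetic", {
  m <- sheepvgg_lite(seed = 1)
  expect_equal(sheepvgg_param_count(m),
               (3 * 3 * 3 * 16 + 16) + (3 * 3 * 16 * 32 + 32) +
                 (20000 * 128 + 128) + (128 * 3 + 3))
  expect_equal(sheepvgg_param_count(m), 2565603)
  expect_equal(dim(m$params$W3), c(20000L, 128L))
})

test_that("the shape chain holds layer by layer", {
  m <- sheepvgg_lite(seed = 2)
  X <- matrix(runif(2 * 30000), 2)
  fwd <- foldear:::svgg_forward(m$params, X)
  expect_equal(nrow(fwd$c1), 100 * 100 * 16)
  expect_equal(nrow(fwd$p1$out), 50 * 50 * 16)
  expect_equal(nrow(fwd$c2), 50 * 50 * 32)
  expect_equal(nrow(fwd$p2$out), 25 * 25 * 32)   # the 20,000-wide flatten
  expect_equal(dim(fwd$fc1), c(2L, 128L))
  expect_equal(dim(fwd$logits), c(2L, 3L))
  zero <- predict(m, array(0, c(100, 100, 3)), type = "logits")
  expect_equal(dim(zero), c(1L, 3L))
})

test_that("serialized 32-bit model stays within the compactness budget", {
  m <- sheepvgg_lite(seed = 3)
  p <- withr::local_tempfile(fileext = ".bin")
  save_sheepvgg(m, p)
  size <- file.info(p)$size
  expect_gt(size, 4 * 2565603)          # all parameters present
  expect_lt(size / 1e6, 11.7)           # compactness bound
  expect_lt(abs(size / 1e6 - 10.26), 0.2)
})

test_that("the learning rate interpolates linearly from 0.001 to 0.0001", {
  cfg <- train_config()
  lr <- lr_schedule(1:50, cfg)
  expect_equal(lr[1], 0.001)
  expect_equal(lr[50], 0.0001)
  expect_equal(lr, 0.001 - (0:49) / 49 * 0.0009, tolerance = 1e-15)
  expect_true(all(diff(lr) < 0))
})

test_that("training learns tiny separable images and logs full history", {
  d <- tiny_images(n_per_class = 8, seed = 71)
  cfg <- train_config(epochs = 8L, batch_size = 8L, seed = 5L)
  m <- train_sheepvgg(sheepvgg_lite(seed = 5), d$images, d$labels, cfg)
  expect_equal(nrow(m$history), 8)
  expect_true(all(c("lr", "train_loss", "val_loss", "val_f1") %in%
                    names(m$history)))
  expect_equal(m$classes, c("foraging", "other", "rumination"))
  acc <- mean(predict(m, d$images) == d$labels)
  expect_gte(acc, 0.95)
  # reproducibility: same seed and data, identical history and weights
  m2 <- train_sheepvgg(sheepvgg_lite(seed = 5), d$images, d$labels, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
})

test_that("training refuses degenerate label sets", {
  d <- tiny_images(n_per_class = 2, seed = 72)
  expect_error(train_sheepvgg(sheepvgg_lite(1), d$images[1:2],
                              rep("other", 2), train_config(epochs = 1)),
               class = "foldear_bad_labels")
})

test_that("deep-feature taps have pinned shapes and the FC1 tap is non-negative", {
  d <- tiny_images(n_per_class = 2, seed = 73)
  m <- sheepvgg_lite(seed = 7)
  fc1 <- extract_deep_features(m, d$images, "FC1")
  fc2 <- extract_deep_features(m, d$images, "FC2")
  expect_equal(dim(fc1), c(6L, 128L))
  expect_equal(dim(fc2), c(6L, 3L))
  expect_true(all(fc1 >= 0))
  expect_identical(fc1, extract_deep_features(m, d$images, "FC1"))
  err <- tryCatch(extract_deep_features(m, d$images, "flatten"),
                  error = conditionMessage)
  expect_match(err, "FC1, FC2")
})

test_that("EigenCAM matches a dense SVD oracle and is scale invariant", {
  set.seed(74)
  A <- matrix(abs(rnorm(625 * 32)), 625, 32)
  hm <- foldear:::heatmap_from_activations(A)
  expect_equal(dim(hm), c(100L, 100L))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(max(hm), 1)
  # oracle: first eigenvector of A'A
  eig <- eigen(crossprod(A), symmetric = TRUE)
  v <- eig$vectors[, 1]
  proj <- as.numeric(A %*% v)
  if (max(proj) <= 0) proj <- -proj
  pkg_proj <- {
    vv <- svd(A, nu = 0, nv = 1)$v[, 1]
    p <- as.numeric(A %*% vv)
    if (max(p) <= 0) -p else p
  }
  expect_lt(max(abs(abs(proj) - abs(pkg_proj))) / max(abs(proj)), 1e-6)
  # rank-1 activations recover the spatial map exactly
  mcol <- abs(rnorm(625))
  cvec <- abs(rnorm(32))
  hm1 <- foldear:::heatmap_from_activations(mcol %o% cvec)
  up <- bilinear_resize(matrix(mcol, 25, 25), 100, 100)
  expect_equal(stats::cor(as.vector(hm1), as.vector(up)), 1,
               tolerance = 1e-10)
  # positive rescaling leaves the heatmap untouched
  expect_equal(hm, foldear:::heatmap_from_activations(A * 37.2),
               tolerance = 1e-9)
  # all-zero activations give a defined all-zero map
  expect_true(all(foldear:::heatmap_from_activations(matrix(0, 625, 32))
                  == 0))
})

test_that("eigencam of a zero image through the model is all zero", {
  m <- sheepvgg_lite(seed = 8)
  hm <- eigencam(m, array(0, c(100, 100, 3)))
  expect_true(all(hm == 0))
})

test_that("serialize/reload reproduces logits bit for bit", {
  d <- tiny_images(n_per_class = 4, seed = 75)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 9L)
  m <- train_sheepvgg(sheepvgg_lite(seed = 9), d$images, d$labels, cfg)
  p <- withr::local_tempfile(fileext = ".bin")
  save_sheepvgg(m, p)
  m2 <- load_sheepvgg(p)
  expect_identical(m$params, m2$params)
  expect_identical(predict(m, d$images, type = "logits"),
                   predict(m2, d$images, type = "logits"))
  expect_identical(m$classes, m2$classes)
  # repeated saves are byte-identical
  p2 <- withr::local_tempfile(fileext = ".bin")
  save_sheepvgg(m, p2)
  expect_identical(readBin(p, raw(), file.info(p)$size),
                   readBin(p2, raw(), file.info(p2)$size))
})
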
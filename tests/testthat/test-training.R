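test_that("patch extraction is deterministic, in-bounds, and exhaustive at patch size", {
  img <- withLocalSeed(3, array(runif(60 * 80 * 3), c(60, 80, 3)))
  p1 <- extractPatches(img, 100, size = 20, seed = 5)
  p2 <- extractPatches(img, 100, size = 20, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1, 100)
  for (p in p1) expect_identical(dim(p), c(20L, 20L, 3L))
  # all patches are genuine sub-blocks: their values occur in the image
  expect_true(all(vapply(p1[1:5], function(p) p[1, 1, 1] %in% img, logical(1))))

  one <- extractPatches(img[1:20, 1:20, , drop = FALSE], 1, size = 20, seed = 9)
  expect_identical(one[[1]], img[1:20, 1:20, , drop = FALSE])
  expect_error(extractPatches(img, 5, size = 100, seed = 1), "smaller")
})

test_that("augmentation generates the 8-element dihedral orbit", {
  patch <- withLocalSeed(7, array(runif(6 * 6 * 3), c(6, 6, 3)))
  aug <- augmentPatch(patch)
  expect_length(aug, 8)
  expect_identical(aug[[1]], patch)
  # pairwise distinct for a generic patch
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(aug[[i]], aug[[j]]))
  # constant patch: all 8 identical
  caug <- augmentPatch(array(0.4, c(4, 4, 3)))
  for (k in 2:8) expect_identical(caug[[k]], caug[[1]])
  # group closure: augmenting any orbit element reproduces the same set
  key <- function(p) paste(signif(as.vector(p), 12), collapse = ",")
  orbit <- sort(vapply(aug, key, character(1)))
  for (k in c(2, 5, 8)) {
    orbit2 <- sort(vapply(augmentPatch(aug[[k]]), key, character(1)))
    expect_identical(orbit2, orbit)
  }
  expect_error(augmentPatch(array(0, c(3, 4, 3))), "square")
})

test_that("the residual loss is a batch mean of squared L2 norms", {
  s <- 4
  yhat <- withLocalSeed(1, array(runif(s * s * 2 * 3), c(s, s, 2, 3)))
  x <- withLocalSeed(2, array(runif(s * s * 2 * 3), c(s, s, 2, 3)))
  # exact residual gives zero loss
  expect_identical(residualLoss(x - yhat, yhat, x), 0)
  # zero residual with yhat == x gives zero
  expect_identical(residualLoss(x * 0, x, x), 0)
  # otherwise strictly positive
  expect_gt(residualLoss(x * 0, yhat, x), 0)
  # scalar loop oracle on a batch of 2
  res <- withLocalSeed(3, array(rnorm(s * s * 2 * 3, sd = 0.1), c(s, s, 2, 3)))
  acc <- 0
  for (b in 1:2) for (cc in 1:3) for (r in 1:s) for (c in 1:s)
    acc <- acc + (res[r, c, b, cc] + yhat[r, c, b, cc] - x[r, c, b, cc])^2
  expect_equal(residualLoss(res, yhat, x), acc / 2, tolerance = 1e-10)
  expect_error(residualLoss(res[, , 1, , drop = FALSE], yhat, x), "shapes")
})

test_that("backpropagated gradients match finite differences", {
  m <- tinyModel(depth = 3L, filters = 4L, seed = 3)
  y <- withLocalSeed(5, array(runif(6 * 6 * 2 * 3), c(6, 6, 2, 3)))
  x <- withLocalSeed(6, array(runif(6 * 6 * 2 * 3), c(6, 6, 2, 3)))
  expect_lt(gradientCheckWorst(m, y, x), 1e-4)
})

test_that("aligned patch pairs agree at measured pixels and augment x8", {
  imgs <- list(withLocalSeed(8, array(runif(40 * 40 * 3), c(40, 40, 3))))
  ds <- prepareTrainingPatches(imgs, patchesPerImage = 3, patchSize = 12,
                               seed = 2, augment = TRUE)
  expect_identical(dim(ds$y), c(12L, 12L, 24L, 3L))  # 3 patches x 8 variants
  expect_identical(dim(ds$x), dim(ds$y))
  # wherever y == x the pixel was either measured or exactly interpolable;
  # roughly half the pixels must match exactly (the measured class)
  frac <- mean(abs(ds$y - ds$x) < 1e-15)
  expect_gt(frac, 0.45)
})

test_that("training is reproducible and reduces the loss on an easy target", {
  imgs <- list(withLocalSeed(4, array(runif(24 * 24 * 3), c(24, 24, 3))))
  ds <- prepareTrainingPatches(imgs, patchesPerImage = 4, patchSize = 10,
                               seed = 3, augment = FALSE)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 4L, steps = 50L,
                     depth = 2L, filters = 4L, patchSize = 10L, seed = 7L)
  fit1 <- trainResidualModel(ds$y, ds$x, cfg)
  fit2 <- trainResidualModel(ds$y, ds$x, cfg)
  expect_identical(fit1$log$loss, fit2$log$loss)
  expect_identical(modelLayers(fit1$model), modelLayers(fit2$model))
  expect_identical(nrow(fit1$log), 50L)
  # non-increasing trend on a 10-step moving average
  ma <- stats::filter(fit1$log$loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
})

test_that("a depth-2 model recovers a linear filter response", {
  # ground truth = bilinear input + fixed 3x3 linear filter response: a
  # tiny network can drive the training loss to a small fraction of the
  # zero-model loss
  K <- array(0, c(3, 3, 3, 3))
  K[2, 2, , ] <- diag(3) * 0.05
  K[1, 2, 1, 1] <- 0.03; K[3, 2, 2, 2] <- -0.03; K[2, 1, 3, 3] <- 0.02
  y <- withLocalSeed(9, array(runif(8 * 8 * 6 * 3), c(8, 8, 6, 3)))
  x <- y * 0
  for (b in 1:6) {
    yb <- y[, , b, , drop = FALSE]
    dim(yb) <- c(8, 8, 1, 3)
    x[, , b, ] <- yb[, , 1, ] + hexdemosaic:::.convForward(yb, K, numeric(3))$out[, , 1, ]
  }
  cfg1 <- trainConfig(learningRate = 1e-2, batchSize = 6L, steps = 800L,
                      depth = 2L, filters = 8L, patchSize = 8L, seed = 2L)
  fit1 <- trainResidualModel(y, x, cfg1)
  # refine at a lower constant rate, warm-starting from the first stage
  cfg2 <- trainConfig(learningRate = 1e-3, batchSize = 6L, steps = 400L,
                      depth = 2L, filters = 8L, patchSize = 8L, seed = 3L)
  fit <- trainResidualModel(y, x, cfg2, model = fit1$model)
  zeroLoss <- residualLoss(y * 0, y, x)  # loss of the zero-residual model
  final <- mean(utils::tail(fit$log$loss, 10))
  expect_lt(final, zeroLoss / 25)
})

test_that("empty or malformed training inputs are rejected", {
  y <- array(0.5, c(6, 6, 2, 3))
  expect_error(trainResidualModel(y, y[, , 1, , drop = FALSE]), "identical shapes")
  expect_error(trainResidualModel(y[, , 1, ], y[, , 1, ]), "S x S x N x 3")
})
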
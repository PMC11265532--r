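test_that("SELU satisfies its analytic contract", {
  p <- seluParams()
  expect_identical(selu(0), 0)
  expect_equal(selu(1), p@lambda)
  # x -> -Inf limit is -lambda * alpha
  expect_equal(selu(-50), -p@lambda * p@alpha, tolerance = 1e-12)
  expect_equal(selu(-Inf), -p@lambda * p@alpha)
  # continuity at 0
  expect_lt(abs(selu(1e-13) - selu(-1e-13)), 1e-12)
  # slope lambda on the positive side
  expect_equal((selu(2) - selu(1)), p@lambda)
  # finite-difference differentiability away from 0, both branches
  for (x0 in c(-1.3, 0.7)) {
    fd <- (selu(x0 + 1e-6) - selu(x0 - 1e-6)) / 2e-6
    expect_equal(fd, hexdemosaic:::.seluGrad(x0, p), tolerance = 1e-6)
  }
  # constants are overridable
  q <- seluParams(lambda = 2, alpha = 1)
  expect_equal(selu(1, q), 2)
  expect_equal(selu(-50, q), -2, tolerance = 1e-12)
})

test_that("an all-zero model predicts an identically zero residual", {
  m <- tinyModel(depth = 3L, filters = 4L)
  ly <- modelLayers(m)
  for (i in seq_along(ly)) { ly[[i]]$W[] <- 0; ly[[i]]$b[] <- 0 }
  modelLayers(m) <- ly
  out <- predictResiduals(m, array(runif(7 * 9 * 3), c(7, 9, 3)))
  expect_true(all(out == 0))
})

test_that("forward pass preserves spatial dimensions at any size", {
  m <- tinyModel(depth = 4L, filters = 5L)
  for (sz in list(c(3, 3), c(3, 11), c(16, 5), c(12, 12))) {
    out <- predictResiduals(m, array(0.3, c(sz, 3)))
    expect_identical(dim(out), as.integer(c(sz, 3)))
  }
  expect_error(predictResiduals(m, array(0.1, c(2, 8, 3))), "receptive field")
  expect_error(predictResiduals(m, array(0.1, c(8, 8, 4))), "channels")
})

test_that("a depth-2 network matches direct convolution arithmetic", {
  # identity normalization: runVar chosen so sqrt(runVar + eps) == 1
  m <- newResidualModel(networkConfig(depth = 2L, filters = 2L), seed = 8)
  ly <- modelLayers(m)
  ly[[1]]$runMean[] <- 0
  ly[[1]]$runVar[] <- 1 - hexdemosaic:::BN_EPS
  modelLayers(m) <- ly
  x <- withLocalSeed(13, array(runif(5 * 5 * 3), c(5, 5, 3)))
  out <- predictResiduals(m, x)

  pad <- function(a) {
    d <- dim(a); p <- array(0, d + c(2, 2, 0))
    p[2:(d[1] + 1), 2:(d[2] + 1), ] <- a
    p
  }
  convOracle <- function(a, W, b) {
    cout <- dim(W)[4]; h <- dim(a)[1]; w <- dim(a)[2]
    p <- pad(a); out <- array(0, c(h, w, cout))
    for (y in 1:h) for (xx in 1:w) for (o in 1:cout) {
      s <- b[o]
      for (i in 1:3) for (j in 1:3) for (c in seq_len(dim(W)[3]))
        s <- s + p[y + i - 1, xx + j - 1, c] * W[i, j, c, o]
      out[y, xx, o] <- s
    }
    out
  }
  h1 <- convOracle(x, ly[[1]]$W, ly[[1]]$b)
  h1 <- selu(h1)                      # normalization is identity here
  expected <- convOracle(h1, ly[[2]]$W, ly[[2]]$b)
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("zeroing the final layer reduces the CNN to the bilinear baseline", {
  m <- zeroFinalLayer(tinyModel(depth = 3L, filters = 6L, seed = 4))
  for (rep in 1:3) {
    fr <- randomFrame(8, 10, phase = rep %% 2, seed = 200 + rep)
    raw <- demosaicCNN(fr, m, clip = FALSE)
    expect_identical(raw, imgData(demosaicBilinear(fr)))
  }
})

test_that("demosaicCNN clips its output to the unit interval", {
  m <- tinyModel(depth = 2L, filters = 4L, seed = 6)  # untrained: large residuals
  rec <- demosaicCNN(randomFrame(8, 8, seed = 2), m)
  expect_s4_class(rec, "MultispectralImage")
  expect_true(min(imgData(rec)) >= 0 && max(imgData(rec)) <= 1)
})

test_that("checkpoint round trip reproduces residuals bit-identically", {
  m <- tinyModel(depth = 3L, filters = 5L, seed = 10)
  # make the running statistics non-trivial before saving
  ly <- modelLayers(m)
  ly[[1]]$runMean <- runif(5) - 0.5
  ly[[1]]$runVar <- runif(5) + 0.5
  modelLayers(m) <- ly
  path <- tempfile(fileext = ".json")
  saveResidualModel(m, path, provenance = list(note = "test"))
  m2 <- loadResidualModel(path)
  expect_identical(modelLayers(m2), modelLayers(m))
  x <- withLocalSeed(19, array(runif(6 * 6 * 3), c(6, 6, 3)))
  expect_identical(predictResiduals(m2, x), predictResiduals(m, x))
  expect_error(suppressWarnings(loadResidualModel(tempfile(fileext = ".json"))))
})
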
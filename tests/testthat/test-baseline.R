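test_that("1D bilinear interpolation matches the per-pixel loop oracle", {
  withLocalSeed(31, {
    for (rep in 1:10) {
      h <- sample(4:12, 1); w <- sample(4:12, 1); ph <- sample(0:1, 1)
      st <- splitFrame(randomFrame(h, w, ph, seed = 100 + rep))
      for (s in st) {
        out <- interpolateStream(s)
        expect_identical(imgData(out), bilinearLoopOracle(s))
      }
    }
  })
})

test_that("measured pixels pass through bit-exactly", {
  st <- splitFrame(randomFrame(9, 9, seed = 7))
  out <- interpolateStream(st$vis)
  sel <- array(rep(validMask(st$vis), 3), c(9, 9, 3))
  expect_identical(imgData(out)[sel], imgData(st$vis)[sel])
})

test_that("a constant stream interpolates to a constant image", {
  m <- makeSamplingMask(6, 6, 0)
  d <- array(0, c(6, 6, 3))
  d[array(rep(visMask(m), 3), c(6, 6, 3))] <- 0.37
  s <- new("SparseChannelImage", data = d, valid = visMask(m))
  expect_true(all(imgData(interpolateStream(s)) == 0.37))
})

test_that("interior missing pixels are horizontal-neighbour means", {
  # row fragment measured [a, _, b] -> middle = (a+b)/2
  m <- makeSamplingMask(2, 3, 0)
  d <- array(0, c(2, 3, 3))
  d[1, 1, ] <- 0.2; d[1, 3, ] <- 0.8   # (0,0) and (0,2) are visible-class
  s <- new("SparseChannelImage", data = d, valid = visMask(m))
  out <- imgData(interpolateStream(s))
  expect_equal(out[1, 2, ], rep(0.5, 3))
  # border column (2,1) is missing and has only a right neighbour (2,2)
  expect_equal(out[2, 1, ], out[2, 2, ])
})

test_that("interpolation is linear and range-preserving per row", {
  st1 <- splitFrame(randomFrame(8, 8, seed = 41))$vis
  st2 <- splitFrame(randomFrame(8, 8, seed = 42))$vis
  a <- 0.3; b <- 0.45
  mix <- new("SparseChannelImage",
             data = a * imgData(st1) + b * imgData(st2),
             valid = validMask(st1))
  lhs <- imgData(interpolateStream(mix))
  rhs <- a * imgData(interpolateStream(st1)) + b * imgData(interpolateStream(st2))
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  out <- imgData(interpolateStream(st1))
  v <- validMask(st1)
  for (r in 1:8) for (cc in 1:3) {
    measured <- imgData(st1)[r, , cc][v[r, ]]
    expect_true(all(out[r, , cc] >= min(measured) - 1e-15))
    expect_true(all(out[r, , cc] <= max(measured) + 1e-15))
  }
})

test_that("row-constant scenes are reconstructed exactly by the 1D scheme", {
  d <- array(0, c(6, 8, 6))
  withLocalSeed(17, for (cc in 1:6) d[, , cc] <- matrix(runif(6), 6, 8))
  img <- MultispectralImage(d)
  rec <- demosaicBilinear(mosaicImage(img, 0))
  expect_equal(imgData(rec), imgData(img), tolerance = 1e-15)
})

test_that("demosaicBilinear composes split and per-stream interpolation", {
  fr <- randomFrame(8, 8, seed = 55)
  rec <- demosaicBilinear(fr)
  st <- splitFrame(fr)
  expect_identical(imgData(rec)[, , 1:3], imgData(interpolateStream(st$vis)))
  expect_identical(imgData(rec)[, , 4:6], imgData(interpolateStream(st$nir)))
})

test_that("the 4-neighbour 2D variant averages all measured neighbours", {
  st <- splitFrame(randomFrame(6, 6, seed = 77))$vis
  out <- imgData(interpolateStream(st, method = "neighbors4"))
  d <- imgData(st); v <- validMask(st)
  for (r in 1:6) for (c in 1:6) {
    if (v[r, c]) next
    nb <- NULL
    if (c > 1) nb <- rbind(nb, d[r, c - 1, ])
    if (c < 6) nb <- rbind(nb, d[r, c + 1, ])
    if (r > 1) nb <- rbind(nb, d[r - 1, c, ])
    if (r < 6) nb <- rbind(nb, d[r + 1, c, ])
    expect_equal(out[r, c, ], colMeans(nb), tolerance = 1e-12)
  }
})
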
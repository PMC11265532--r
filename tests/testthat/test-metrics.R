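test_that("MSE and PSNR satisfy their closed forms", {
  a <- withLocalSeed(1, array(runif(8 * 8 * 3), c(8, 8, 3)))
  expect_identical(channelMSE(a, a), rep(0, 3))
  expect_identical(psnr(a, a), rep(Inf, 3))
  # constant offset d -> MSE d^2
  expect_equal(channelMSE(a, pmin(a + 0.1, Inf)), rep(0.01, 3), tolerance = 1e-12)
  # uniform error 0.1 / 0.01 on peak-1 scale -> 20 / 40 dB
  expect_equal(psnr(a, a + 0.1), rep(20, 3), tolerance = 1e-9)
  expect_equal(psnr(a, a + 0.01), rep(40, 3), tolerance = 1e-9)
  # scalar double-loop oracle
  b <- withLocalSeed(2, array(runif(8 * 8 * 3), c(8, 8, 3)))
  for (cc in 1:3) {
    acc <- 0
    for (r in 1:8) for (c in 1:8) acc <- acc + (a[r, c, cc] - b[r, c, cc])^2
    expect_equal(channelMSE(a, b)[cc], acc / 64, tolerance = 1e-12)
  }
  expect_error(channelMSE(a, b[1:4, , ]), "identical shapes")
  expect_error(psnr(a, b, peak = 0), "positive")
})

test_that("DSSIM percentile follows the windowed SSIM definition", {
  a <- withLocalSeed(3, matrix(runif(15 * 15), 15, 15))
  expect_equal(dssimP95(a, a), 0, tolerance = 1e-12)

  # independent per-pixel oracle: direct 11x11 Gaussian-weighted sums with
  # mirror padding (no separability, no vectorization)
  b <- pmin(pmax(a + withLocalSeed(4, matrix(rnorm(225, sd = 0.1), 15, 15)), 0), 1)
  g1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  g2 <- outer(g1, g1)
  ref <- function(m, r, c) {
    # mirror-reflected lookup
    ri <- r; ci <- c
    if (ri < 1) ri <- 1 - ri
    if (ri > 15) ri <- 2 * 15 + 1 - ri
    if (ci < 1) ci <- 1 - ci
    if (ci > 15) ci <- 2 * 15 + 1 - ci
    m[ri, ci]
  }
  wsum <- function(m, r, c) {
    s <- 0
    for (i in -5:5) for (j in -5:5)
      s <- s + g2[i + 6, j + 6] * ref(m, r + i, c + j)
    s
  }
  c1 <- 0.01^2; c2 <- 0.03^2
  dssimMapOracle <- matrix(0, 15, 15)
  for (r in 1:15) for (c in 1:15) {
    mu1 <- wsum(a, r, c); mu2 <- wsum(b, r, c)
    s11 <- wsum(a * a, r, c) - mu1^2
    s22 <- wsum(b * b, r, c) - mu2^2
    s12 <- wsum(a * b, r, c) - mu1 * mu2
    ss <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
      ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
    dssimMapOracle[r, c] <- (1 - ss) / 2
  }
  expect_equal(dssimP95(a, b),
               unname(stats::quantile(dssimMapOracle, 0.95, type = 7)),
               tolerance = 1e-10)
  # p95 dominates the median of the map
  expect_gte(dssimP95(a, b), dssimP95(a, b, probs = 0.5))
})

test_that("contrast inversion of a structured binary image maximizes DSSIM", {
  a <- matrix(0, 16, 16)
  a[, seq(1, 16, by = 4)] <- 1      # structured stripes
  a[seq(1, 16, by = 3), ] <- 1
  expect_gt(dssimP95(a, 1 - a), 0.8)
})

test_that("the colour difference is a normalized channel-space distance", {
  a <- withLocalSeed(5, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(deltaEP95(a, a), 0)
  expect_equal(deltaEP95(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))), 100)
  b <- withLocalSeed(6, array(runif(16 * 16 * 3), c(16, 16, 3)))
  de <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16)
    de[r, c] <- sqrt(sum((a[r, c, ] - b[r, c, ])^2)) / sqrt(3) * 100
  expect_equal(deltaEP95(a, b),
               unname(stats::quantile(de, 0.95, type = 7)), tolerance = 1e-12)
  # symmetry of mse, deltaE, and the SSIM formula
  expect_identical(channelMSE(a, b), channelMSE(b, a))
  expect_identical(deltaEP95(a, b), deltaEP95(b, a))
  expect_equal(dssimP95(a, b), dssimP95(b, a), tolerance = 1e-12)
  # CIE76 Lab variant runs and is non-negative
  expect_gte(deltaEP95(a, b, method = "lab"), 0)
})

test_that("metrics degrade monotonically with noise amplitude", {
  a <- imgData(generateScene(sceneSpec(seed = 12, noiseSigma = 0)))[, , 1:3]
  noise <- withLocalSeed(13, array(rnorm(length(a)), dim(a)))
  amps <- c(0.01, 0.05, 0.15)
  ms <- de <- ds <- numeric(3)
  for (k in 1:3) {
    b <- pmin(pmax(a + amps[k] * noise, 0), 1)
    ms[k] <- mean(channelMSE(a, b)); de[k] <- deltaEP95(a, b)
    ds[k] <- dssimP95(a, b)
  }
  expect_true(all(diff(ms) > 0))
  expect_true(all(diff(de) > 0))
  expect_true(all(diff(ds) >= 0))
})

test_that("frequency comparison isolates lost vertical-frequency content", {
  a <- withLocalSeed(7, matrix(runif(32 * 32), 32, 32))
  fp <- frequencyCompare(a, a)
  expect_true(all(fp@diffProfile == 0))
  expect_length(fp@profile, 32)

  # conjugate symmetry of the real-image spectrum: magnitude is symmetric
  # under frequency negation
  f <- stats::fft(a)
  for (k in c(2, 5, 11)) for (l in c(3, 8)) {
    expect_equal(Mod(f[k, l]), Mod(f[32 - k + 2, 32 - l + 2]), tolerance = 1e-9)
  }

  # a pure sinusoid along rows vs. its vertically blurred copy: the
  # deficit concentrates at the stripe frequency
  h <- 64; kf <- 24
  s <- matrix(rep(0.5 + 0.4 * sin(2 * pi * kf * (0:(h - 1)) / h), 16), h, 16)
  blur <- s
  for (r in 2:(h - 1)) blur[r, ] <- (s[r - 1, ] + s[r, ] + s[r + 1, ]) / 3
  fp2 <- frequencyCompare(blur, s)
  at <- which.min(abs(fp2@freq - kf / h))
  away <- which.min(abs(fp2@freq - 2 / h))
  expect_lt(fp2@diffProfile[at], -3)            # strong deficit at the stripe
  expect_gt(fp2@diffProfile[away], -1)          # low frequencies preserved
  expect_gt(highFrequencyDeficit(fp2), 0)
})

test_that("evaluateReconstruction assembles a consistent report", {
  truth <- generateScene(sceneSpec(seed = 21))
  rep0 <- evaluateReconstruction(truth, truth)
  expect_true(all(rep0@mse == 0))
  expect_true(all(rep0@psnr == Inf))
  expect_true(all(rep0@dssimP95 < 1e-12))
  expect_true(all(rep0@deltaEP95 == 0))

  rec <- demosaicBilinear(mosaicImage(truth, 0))
  rp <- evaluateReconstruction(rec, truth)
  ok <- rp@mse > 0
  expect_true(all(abs(rp@psnr[ok] - 10 * log10(1 / rp@mse[ok])) < 1e-9))
  expect_named(rp@mse, c("vis_r", "vis_g", "vis_b", "nir_1", "nir_2", "nir_3"))

  # serialization: JSON schema and CSV round trip
  jp <- tempfile(fileext = ".json")
  writeMetricReport(rp, jp)
  doc <- jsonlite::read_json(jp)
  expect_setequal(names(doc), c("psnr_db", "mse", "dssim_p95",
                                "delta_e_p95_percent"))
  cp <- tempfile(fileext = ".csv")
  writeMetricReport(rp, cp)
  df <- utils::read.csv(cp)
  expect_identical(names(df), c("metric", "channel", "value"))
  expect_identical(nrow(df), 16L)
})
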
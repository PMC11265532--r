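# deterministic random fixtures used across test files

randomImage6 <- function(h, w, seed = 1) {
  withLocalSeed(seed, MultispectralImage(array(runif(h * w * 6), c(h, w, 6))))
}

randomFrame <- function(h, w, phase = 0L, seed = 1) {
  mosaicImage(randomImage6(h, w, seed), phase)
}

tinyModel <- function(depth = 3L, filters = 4L, seed = 3) {
  newResidualModel(networkConfig(depth = depth, filters = filters), seed = seed)
}

# zero the final (residual-producing) layer of a model
zeroFinalLayer <- function(model) {
  n <- modelConfig(model)@depth
  ly <- modelLayers(model)
  ly[[n]]$W[] <- 0
  ly[[n]]$b[] <- 0
  modelLayers(model) <- ly
  model
}

# per-pixel loop oracle for 1D horizontal bilinear interpolation
bilinearLoopOracle <- function(sparse) {
  d <- imgData(sparse)
  v <- validMask(sparse)
  h <- dim(d)[1]; w <- dim(d)[2]
  out <- d
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (v[r, c]) next
    nb <- NULL
    if (c > 1) nb <- rbind(nb, d[r, c - 1, ])
    if (c < w) nb <- rbind(nb, d[r, c + 1, ])
    out[r, c, ] <- colMeans(nb)
  }
  out
}

# finite-difference check of the analytic gradients on a tiny model;
# returns the worst relative error over sampled coordinates (coordinates
# where both gradients are ~0, e.g. conv biases absorbed by batch
# normalization, count as exact)
gradientCheckWorst <- function(model, y, x, perParam = 4L, eps = 1e-6,
                               seed = 11) {
  lg <- hexdemosaic:::.lossGradients(model, y, x)
  worst <- 0
  withLocalSeed(seed, {
    for (ly in seq_along(modelLayers(model))) {
      for (p in names(lg$grads[[ly]])) {
        arr <- modelLayers(model)[[ly]][[p]]
        for (k in sample(length(arr), min(perParam, length(arr)))) {
          m2 <- model
          m2@layers[[ly]][[p]][k] <- arr[k] + eps
          lp <- hexdemosaic:::.lossGradients(m2, y, x)$loss
          m2@layers[[ly]][[p]][k] <- arr[k] - eps
          lm <- hexdemosaic:::.lossGradients(m2, y, x)$loss
          fd <- (lp - lm) / (2 * eps)
          an <- lg$grads[[ly]][[p]][k]
          if (abs(fd) < 1e-6 && abs(an) < 1e-6) next
          worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an)))
        }
      }
    }
  })
  worst
}
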
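#' Extract random square patches from a 3-channel image
#'
#' Patches are placed at uniformly random top-left offsets (sampled with
#' replacement) under the given seed, so the same seed always yields the
#' same patch set.
#'
#' @param image H x W x 3 numeric array (or an
#'   \linkS4class{InterpolatedImage}).
#' @param n number of patches.
#' @param size square patch side in pixels (reference recipe: 50).
#' @param seed integer RNG seed.
#' @return List of \code{n} size x size x 3 arrays.
#' @export
extractPatches <- function(image, n, size = 50L, seed = 1L) {
  if (is(image, "InterpolatedImage")) image <- image@data
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  size <- as.integer(size)
  if (d[1] < size || d[2] < size)
    stop(sprintf("image (%d x %d) smaller than the %d-pixel patch", d[1], d[2], size))
  withLocalSeed(seed, {
    r0 <- sample.int(d[1] - size + 1L, n, replace = TRUE)
    c0 <- sample.int(d[2] - size + 1L, n, replace = TRUE)
    lapply(seq_len(n), function(i)
      image[r0[i]:(r0[i] + size - 1L), c0[i]:(c0[i] + size - 1L), , drop = FALSE])
  })
}

#' The 8 dihedral variants of a square patch
#'
#' Data augmentation of the training recipe: the four 90-degree rotations
#' of the patch and the horizontal flip of each -- the full dihedral group
#' of the square (the original is element 1).
#'
#' @param patch square S x S x C numeric array.
#' @return List of 8 patches.
#' @export
augmentPatch <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || d[1] != d[2]) stop("patch must be square (S x S x C)")
  rot90 <- function(p) {
    # counter-clockwise quarter turn: new[i, j] = old[j, S - i + 1]
    aperm(p[, d[1]:1, , drop = FALSE], c(2L, 1L, 3L))
  }
  hflip <- function(p) p[, d[1]:1, , drop = FALSE]
  out <- vector("list", 8L)
  cur <- patch
  for (k in 1:4) {
    out[[k]] <- cur
    out[[k + 4L]] <- hflip(cur)
    if (k < 4L) cur <- rot90(cur)
  }
  out
}

#' Residual learning loss
#'
#' The training objective: the mean over the batch of the squared L2 norms
#' of the reconstruction errors,
#' \code{mean_i || (residual_i + yhat_i) - x_i ||^2}, where \code{residual}
#' is the network prediction, \code{yhat} the bilinearly interpolated patch
#' and \code{x} the ground truth. Zero exactly when every reconstruction is
#' exact.
#'
#' @param residual,yhat,x aligned numeric arrays; either single patches
#'   (S x S x C) or batches (S x S x B x C).
#' @return Non-negative scalar loss.
#' @export
residualLoss <- function(residual, yhat, x) {
  if (!identical(dim(residual), dim(yhat)) || !identical(dim(residual), dim(x)))
    stop("residual, yhat and x must have identical shapes")
  nb <- if (length(dim(x)) == 4L) dim(x)[3] else 1L
  err <- residual + yhat - x
  sum(err * err) / nb
}

# loss + parameter gradients on one batch (training-mode normalization).
# y, x: S x S x B x C arrays. Used by the optimizer and the
# finite-difference gradient checks. Also returns the per-layer batch
# statistics so the training loop can maintain running estimates without a
# second forward pass.
.lossGradients <- function(model, y, x) {
  fwd <- .forwardPass(model, y, training = TRUE, keepCache = TRUE)
  nb <- dim(x)[3]
  err <- fwd$out + y - x
  loss <- sum(err * err) / nb
  grads <- .backwardPass(model, fwd$caches, 2 * err / nb)
  bnStats <- lapply(fwd$caches[seq_len(model@config@depth - 1L)],
                    function(cc) list(mu = cc$bn$mu, v = cc$bn$v, m = cc$bn$m))
  list(loss = loss, grads = grads, bnStats = bnStats)
}

#' Assemble aligned training patch batches from full-resolution images
#'
#' Simulates the sensing pipeline on 3-channel ground-truth images: each
#' image is checkerboard-sampled as one stream, filled by 1D bilinear
#' interpolation, and random aligned (bilinear, truth) patch pairs are cut
#' from the result, optionally expanded by the 8-element dihedral
#' augmentation. This mirrors training on ordinary colour photographs; the
#' identical pipeline applies to NIR ground truth.
#'
#' @param images list of H x W x 3 arrays in [0, 1].
#' @param patchesPerImage random patches per image.
#' @param patchSize patch side.
#' @param seed RNG seed.
#' @param augment apply \code{\link{augmentPatch}} to every pair.
#' @param phase checkerboard phase used for the simulated sampling.
#' @return List with 4D arrays \code{y} (bilinear) and \code{x} (truth) of
#'   dim S x S x N x 3.
#' @export
prepareTrainingPatches <- function(images, patchesPerImage = 100L,
                                   patchSize = 50L, seed = 1L,
                                   augment = TRUE, phase = 0L) {
  if (length(images) < 1L) stop("need at least one training image")
  ys <- list(); xs <- list()
  for (k in seq_along(images)) {
    img <- images[[k]]
    d <- dim(img)
    mask <- makeSamplingMask(d[1], d[2], phase)
    sp <- img
    sp[!.rep3(mask@visMask)] <- 0
    sparse <- new("SparseChannelImage", data = sp, valid = mask@visMask)
    yhat <- interpolateStream(sparse)@data
    pseed <- seed + 7919L * k
    py <- extractPatches(yhat, patchesPerImage, patchSize, seed = pseed)
    px <- extractPatches(img, patchesPerImage, patchSize, seed = pseed)
    if (augment) {
      py <- do.call(c, lapply(py, augmentPatch))
      px <- do.call(c, lapply(px, augmentPatch))
    }
    ys <- c(ys, py); xs <- c(xs, px)
  }
  n <- length(ys); s <- dim(ys[[1]])[1]
  yArr <- array(0, c(s, s, n, 3L)); xArr <- array(0, c(s, s, n, 3L))
  for (i in seq_len(n)) {
    yArr[, , i, ] <- ys[[i]]
    xArr[, , i, ] <- xs[[i]]
  }
  list(y = yArr, x = xArr)
}

#' Train a residual demosaicing model
#'
#' Optimizes the residual objective with Adam (constant learning rate,
#' beta1 = 0.9, beta2 = 0.999) from an MSRA initialization. Batches are
#' sampled with replacement from the patch pool under the configured seed,
#' so a run is reproducible. Normalization layers use batch statistics
#' during optimization and accumulate running statistics for inference.
#'
#' @param y,x aligned 4D patch arrays (S x S x N x 3) as produced by
#'   \code{\link{prepareTrainingPatches}}.
#' @param config a \linkS4class{TrainConfig}.
#' @param model optional warm-start \linkS4class{ResidualModel}; by default
#'   a fresh MSRA-initialized model of the configured depth/filters.
#' @param verbose log the loss every 50 steps.
#' @return List with the trained \code{model} and a \code{log} data frame
#'   (step, loss, lr).
#' @export
trainResidualModel <- function(y, x, config = trainConfig(), model = NULL,
                               verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"))
  if (!identical(dim(y), dim(x)))
    stop("y and x must have identical shapes")
  if (length(dim(y)) != 4L) stop("y and x must be S x S x N x 3 arrays")
  n <- dim(y)[3]
  if (n < 1L) stop("empty training set")
  if (is.null(model))
    model <- newResidualModel(networkConfig(depth = config@depth,
                                            filters = config@filters),
                              seed = config@seed)
  paramNames <- c("W", "b", "gamma", "beta")
  mState <- lapply(model@layers, function(ly)
    lapply(ly[intersect(paramNames, names(ly))], function(p) p * 0))
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config@learningRate
  log <- data.frame(step = integer(config@steps), loss = numeric(config@steps),
                    lr = numeric(config@steps))
  batches <- withLocalSeed(config@seed + 1L, {
    lapply(seq_len(config@steps), function(i)
      sample.int(n, min(config@batchSize, n), replace = TRUE))
  })
  for (step in seq_len(config@steps)) {
    idx <- batches[[step]]
    yb <- y[, , idx, , drop = FALSE]
    xb <- x[, , idx, , drop = FALSE]
    lg <- .lossGradients(model, yb, xb)
    if (!is.finite(lg$loss))
      stop(sprintf("training diverged at step %d (loss = %g); lower the learning rate",
                   step, lg$loss))
    t <- step
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    for (ly in seq_along(model@layers)) {
      for (p in names(mState[[ly]])) {
        g <- lg$grads[[ly]][[p]]
        mState[[ly]][[p]] <- beta1 * mState[[ly]][[p]] + (1 - beta1) * g
        vState[[ly]][[p]] <- beta2 * vState[[ly]][[p]] + (1 - beta2) * g * g
        model@layers[[ly]][[p]] <- model@layers[[ly]][[p]] -
          lr * (mState[[ly]][[p]] / bc1) / (sqrt(vState[[ly]][[p]] / bc2) + eps)
      }
      if (ly < model@config@depth) {
        st <- lg$bnStats[[ly]]
        unb <- if (st$m > 1L) st$m / (st$m - 1L) else 1
        model@layers[[ly]]$runMean <-
          (1 - BN_MOMENTUM) * model@layers[[ly]]$runMean + BN_MOMENTUM * st$mu
        model@layers[[ly]]$runVar <-
          (1 - BN_MOMENTUM) * model@layers[[ly]]$runVar + BN_MOMENTUM * st$v * unb
      }
    }
    log$step[step] <- step; log$loss[step] <- lg$loss; log$lr[step] <- lr
    if (verbose && (step %% 50L == 0L || step == 1L))
      .logMsg("INFO", sprintf("step %d loss %.6g", step, lg$loss))
  }
  list(model = model, log = log)
}
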
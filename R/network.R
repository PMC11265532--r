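#' Scaled exponential linear unit
#'
#' \code{selu(x) = lambda * x} for \code{x > 0} and
#' \code{lambda * alpha * (exp(x) - 1)} for \code{x <= 0}. The default
#' constants are the canonical self-normalizing values
#' (lambda = 1.0507009873554805, alpha = 1.6732632423543772).
#'
#' @param x numeric vector/array.
#' @param params a \linkS4class{SeluParams}.
#' @return Elementwise activation, same shape as \code{x}.
#' @examples
#' selu(c(-Inf, 0, 1))
#' @export
selu <- function(x, params = seluParams()) {
  params@lambda * (pmax(x, 0) + params@alpha * (exp(pmin(x, 0)) - 1))
}

# derivative of selu, elementwise
.seluGrad <- function(x, params) {
  pos <- x > 0
  params@lambda * (pos + (!pos) * (params@alpha * exp(pmin(x, 0))))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Initialize a residual model with MSRA (He) weights
#'
#' Convolution weights are drawn from N(0, 2 / fan_in) with
#' fan_in = kernel^2 * input channels; biases are zero; batch-normalization
#' scale/shift start at 1/0 with running statistics 0/1.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param selu a \linkS4class{SeluParams}.
#' @param seed integer RNG seed for the weight draw.
#' @return A \linkS4class{ResidualModel}.
#' @examples
#' m <- newResidualModel(networkConfig(depth = 5L, filters = 8L), seed = 1)
#' @export
newResidualModel <- function(config = networkConfig(), selu = seluParams(),
                             seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  layers <- withLocalSeed(seed, {
    lapply(seq_len(config@depth), function(n) {
      cin <- if (n == 1L) config@channels else config@filters
      cout <- if (n == config@depth) config@channels else config@filters
      k <- config@kernel
      sd <- sqrt(2 / (k * k * cin))
      ly <- list(W = array(stats::rnorm(k * k * cin * cout, sd = sd),
                           c(k, k, cin, cout)),
                 b = numeric(cout))
      if (n < config@depth) {
        ly$gamma <- rep(1, cout); ly$beta <- numeric(cout)
        ly$runMean <- numeric(cout); ly$runVar <- rep(1, cout)
      }
      ly
    })
  })
  new("ResidualModel", layers = layers, config = config, selu = selu)
}

# ---- convolution primitives -------------------------------------------------
# Feature maps are stored as H x W x B x C arrays so that dropping the dim
# attribute yields an (H*W*B) x C matrix (column-major order) and the heavy
# lifting becomes 9 GEMMs per layer, one per kernel tap.

.pad1 <- function(a) {
  d <- dim(a)
  p <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  p[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- a
  p
}

# cache of im2col gather indices, keyed by activation shape
.idxCache <- new.env(parent = emptyenv())

# integer index vector such that the unfolded (H*W*B) x (cin*9) patch
# matrix is pad[idx]: the columns for kernel tap (i, j) occupy the
# contiguous block ((q-1)*cin + 1):(q*cin) with q = i + 3*(j-1), input
# channel fastest within a block. The matching kernel matrix is
# aperm(W, c(3, 1, 2, 4)) flattened to (cin*9) x cout, so the whole
# convolution is a single GEMM over a single gather.
.im2colIdx <- function(h, w, nb, cin) {
  key <- paste(h, w, nb, cin, sep = "x")
  idx <- .idxCache[[key]]
  if (!is.null(idx)) return(idx)
  hp <- h + 2L; wp <- w + 2L
  # linear index of pad[y+0, x+0, b, 1] for tap (1,1)
  base0 <- as.vector(outer(outer(seq_len(h), hp * (seq_len(w) - 1L), "+"),
                           hp * wp * (seq_len(nb) - 1L), "+"))
  tapOff <- as.vector(outer(0:2, hp * (0:2), "+"))          # q = i + 3*(j-1)
  chanOff <- hp * wp * nb * (seq_len(cin) - 1L)
  off <- rep(tapOff, each = cin) + rep.int(chanOff, 9L)
  idx <- rep.int(as.integer(base0), 9L * cin) +
    rep(as.integer(off), each = length(base0))
  .idxCache[[key]] <- idx
  idx
}

.im2col <- function(a) {
  d <- dim(a); h <- d[1]; w <- d[2]; nb <- d[3]; cin <- d[4]
  p <- .pad1(a)
  col <- p[.im2colIdx(h, w, nb, cin)]
  dim(col) <- c(h * w * nb, 9L * cin)
  col
}

.kernelMatrix <- function(W) {
  cin <- dim(W)[3]; cout <- dim(W)[4]
  Wm <- aperm(W, c(3L, 1L, 2L, 4L))
  dim(Wm) <- c(9L * cin, cout)
  Wm
}

# correlation with 3x3 kernel W (3 x 3 x cin x cout), one-pixel zero padding
.convForward <- function(a, W, b) {
  d <- dim(a); h <- d[1]; w <- d[2]; nb <- d[3]
  cout <- dim(W)[4]
  col <- .im2col(a)
  out <- col %*% .kernelMatrix(W)
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(h, w, nb, cout)
  list(out = out, col = col, shape = c(h, w, nb))
}

# gradients of the convolution given the cached im2col matrix. The input
# gradient is itself a same-padded correlation of dOut with the spatially
# flipped, channel-transposed kernel, so it reuses the fast forward path.
.convBackward <- function(col, shape, W, dOut, needInputGrad = TRUE) {
  h <- shape[1]; w <- shape[2]; nb <- shape[3]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  dOutM <- dOut
  dim(dOutM) <- c(h * w * nb, cout)
  dWm <- crossprod(col, dOutM)              # (cin*9) x cout
  dim(dWm) <- c(cin, 3L, 3L, cout)
  dW <- aperm(dWm, c(2L, 3L, 1L, 4L))
  db <- colSums(dOutM)
  dA <- NULL
  if (needInputGrad) {
    Wt <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dim(dOut) <- c(h, w, nb, cout)
    dA <- .convForward(dOut, Wt, numeric(cin))$out
  }
  list(dW = dW, db = db, dA = dA)
}

# batch normalization over all pixels/samples per channel
.bnForward <- function(a, ly, training) {
  d <- dim(a)
  m <- d[1] * d[2] * d[3]
  x <- a
  dim(x) <- c(m, d[4])
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- ly$runMean
    v <- ly$runVar
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  scale <- ly$gamma * invstd
  shift <- ly$beta - mu * scale
  y <- x * rep(scale, each = m) + rep(shift, each = m)
  dim(y) <- d
  list(out = y, x = x, mu = mu, v = v, invstd = invstd, m = m)
}

.bnBackward <- function(cache, ly, dOut) {
  d <- dim(dOut)
  dy <- dOut
  m <- cache$m
  dim(dy) <- c(m, d[4])
  xhat <- (cache$x - rep(cache$mu, each = m)) * rep(cache$invstd, each = m)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(ly$gamma, each = m)
  s1 <- colSums(dxhat) / m
  s2 <- colSums(dxhat * xhat) / m
  dx <- (dxhat - rep(s1, each = m) - xhat * rep(s2, each = m)) *
    rep(cache$invstd, each = m)
  dim(dx) <- d
  list(dA = dx, dgamma = dgamma, dbeta = dbeta)
}

# full forward pass over a batch array (H x W x B x channels).
# training = TRUE uses batch statistics in the normalization layers and
# returns the caches needed for backpropagation.
.forwardPass <- function(model, batch, training = FALSE, keepCache = FALSE) {
  cfg <- model@config
  n <- cfg@depth
  caches <- if (keepCache) vector("list", n) else NULL
  a <- batch
  for (ly in seq_len(n)) {
    par <- model@layers[[ly]]
    cv <- .convForward(a, par$W, par$b)
    if (ly < n) {
      bn <- .bnForward(cv$out, par, training)
      z <- bn$out
      a <- model@selu@lambda *
        (pmax(z, 0) + model@selu@alpha * (exp(pmin(z, 0)) - 1))
      if (keepCache) caches[[ly]] <- list(col = cv$col, shape = cv$shape,
                                          bn = bn, z = z)
    } else {
      a <- cv$out
      if (keepCache) caches[[ly]] <- list(col = cv$col, shape = cv$shape)
    }
  }
  list(out = a, caches = caches)
}

# backward pass; dOut is the gradient of the loss w.r.t. the network output.
# Returns per-layer gradients mirroring the layer parameter lists.
.backwardPass <- function(model, caches, dOut) {
  cfg <- model@config
  n <- cfg@depth
  grads <- vector("list", n)
  dA <- dOut
  for (ly in rev(seq_len(n))) {
    par <- model@layers[[ly]]
    cache <- caches[[ly]]
    if (ly < n) {
      dZ <- dA * .seluGrad(cache$z, model@selu)
      bnb <- .bnBackward(cache$bn, par, dZ)
      cvb <- .convBackward(cache$col, cache$shape, par$W, bnb$dA,
                           needInputGrad = ly > 1L)
      grads[[ly]] <- list(W = cvb$dW, b = cvb$db,
                          gamma = bnb$dgamma, beta = bnb$dbeta)
    } else {
      cvb <- .convBackward(cache$col, cache$shape, par$W, dA,
                           needInputGrad = ly > 1L)
      grads[[ly]] <- list(W = cvb$dW, b = cvb$db)
    }
    dA <- cvb$dA
  }
  grads
}

#' Predict high-frequency residuals for an interpolated stream
#'
#' Runs the residual network in inference mode (normalization layers use
#' their stored running statistics). Hidden layers apply convolution,
#' batch normalization and the SELU activation; the final layer is a plain
#' convolution with three filters and no activation. One-pixel padding
#' preserves the spatial dimensions throughout.
#'
#' @param model a \linkS4class{ResidualModel}.
#' @param input an \linkS4class{InterpolatedImage} or an H x W x 3 array.
#' @return H x W x 3 numeric array of predicted residuals.
#' @export
predictResiduals <- function(model, input) {
  stopifnot(is(model, "ResidualModel"))
  a <- if (is(input, "InterpolatedImage")) input@data else input
  d <- dim(a)
  if (length(d) != 3L || d[3] != model@config@channels)
    stop("input must be an H x W x 3 array matching the model channels")
  if (d[1] < model@config@kernel || d[2] < model@config@kernel)
    stop("input smaller than the receptive field")
  dim(a) <- c(d[1], d[2], 1L, d[3])
  out <- .forwardPass(model, a, training = FALSE)$out
  dim(out) <- d
  out
}

#' Demosaic a raw frame with the residual network
#'
#' The full reconstruction operator: each half-resolution stream is first
#' filled by 1D bilinear interpolation, the residual network then predicts
#' the high-frequency correction from the interpolated stream, and the two
#' are summed. Separate models may be supplied for the visible and NIR
#' streams; by default the NIR stream reuses the visible (colour-trained)
#' model, mirroring a network trained primarily on colour imagery.
#'
#' @param frame a \linkS4class{MosaicFrame}.
#' @param visModel a \linkS4class{ResidualModel} for the visible stream.
#' @param nirModel model for the NIR stream (default: \code{visModel}).
#' @param clip clip the output to [0, 1] (default TRUE). Disable to obtain
#'   the raw sum, which equals the bilinear baseline exactly when the
#'   model's final-layer parameters are zero.
#' @return A \linkS4class{MultispectralImage} (values clipped to [0, 1]
#'   unless \code{clip = FALSE}, in which case construction is bypassed and
#'   a plain H x W x 6 array is returned).
#' @export
demosaicCNN <- function(frame, visModel, nirModel = visModel, clip = TRUE) {
  stopifnot(is(frame, "MosaicFrame"), is(visModel, "ResidualModel"),
            is(nirModel, "ResidualModel"))
  streams <- splitFrame(frame)
  vis <- interpolateStream(streams$vis)
  nir <- interpolateStream(streams$nir)
  h <- dim(vis@data)[1]; w <- dim(vis@data)[2]
  out <- array(0, c(h, w, 6L))
  out[, , 1:3] <- vis@data + predictResiduals(visModel, vis)
  out[, , 4:6] <- nir@data + predictResiduals(nirModel, nir)
  if (!clip) return(out)
  out[out < 0] <- 0
  out[out > 1] <- 1
  MultispectralImage(out, meta = list(method = "residual_cnn",
                                      phase = frame@phase))
}

# ---- serialization ----------------------------------------------------------

.encodeArray <- function(x) {
  list(dim = as.integer(if (is.null(dim(x))) length(x) else dim(x)),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8L, endian = "little")))
}

.decodeArray <- function(e) {
  dims <- as.integer(unlist(e$dim))
  v <- readBin(jsonlite::base64_dec(e$data), numeric(),
               n = prod(dims), size = 8L, endian = "little")
  if (length(dims) > 1L) dim(v) <- dims
  v
}

#' Save / load a residual model checkpoint
#'
#' The checkpoint is a single JSON document holding the architecture, the
#' SELU constants and every parameter array (base64-encoded IEEE doubles,
#' little-endian), so that save -> load -> forward is bit-identical.
#'
#' @param model a \linkS4class{ResidualModel}.
#' @param path file path of the checkpoint.
#' @param provenance optional list stored verbatim in the manifest (e.g.
#'   training seed and dataset description).
#' @return \code{saveResidualModel} returns \code{path} invisibly;
#'   \code{loadResidualModel} returns the restored model.
#' @export
saveResidualModel <- function(model, path, provenance = list()) {
  stopifnot(is(model, "ResidualModel"))
  cfg <- model@config
  doc <- list(
    format = "hexdemosaic-checkpoint-1",
    config = list(depth = cfg@depth, filters = cfg@filters,
                  kernel = cfg@kernel, channels = cfg@channels),
    selu = list(lambda = .encodeArray(model@selu@lambda),
                alpha = .encodeArray(model@selu@alpha)),
    provenance = provenance,
    layers = lapply(model@layers, function(ly) lapply(ly, .encodeArray)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveResidualModel
#' @export
loadResidualModel <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "hexdemosaic-checkpoint-1"))
    stop("not a hexdemosaic checkpoint: ", path)
  cfg <- networkConfig(depth = doc$config$depth, filters = doc$config$filters,
                       channels = doc$config$channels)
  layers <- lapply(doc$layers, function(ly) lapply(ly, .decodeArray))
  new("ResidualModel", layers = layers, config = cfg,
      selu = seluParams(lambda = .decodeArray(doc$selu$lambda),
                        alpha = .decodeArray(doc$selu$alpha)))
}
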
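#' @import methods
NULL

CHANNEL_NAMES <- c("vis_r", "vis_g", "vis_b", "nir_1", "nir_2", "nir_3")

.checkFinite <- function(x, what) {
  if (!all(is.finite(x))) sprintf("%s contains non-finite values", what) else NULL
}

#' MultispectralImage: a 6-channel visible + NIR ground-truth image
#'
#' Container for a full-resolution hexachromatic image: three visible
#' channels (400-700 nm analogues of R, G, B) followed by three
#' near-infrared channels (700-1000 nm). Pixel values are stored as real
#' numbers on the unit interval, the working scale of the whole package.
#'
#' @slot data numeric H x W x 6 array with all values in [0, 1].
#' @slot meta list of free-form provenance (e.g. the generating scene
#'   specification and the placed structures for synthetic scenes).
#' @exportClass MultispectralImage
setClass("MultispectralImage",
  representation(data = "array", meta = "list"),
  prototype(meta = list()),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 6L)
      return("data must be an H x W x 6 array")
    if (dim(d)[1] < 2L || dim(d)[2] < 2L)
      return("image must be at least 2 x 2 pixels")
    msg <- .checkFinite(d, "data")
    if (!is.null(msg)) return(msg)
    if (min(d) < 0 || max(d) > 1)
      return("pixel values must lie in [0, 1]")
    TRUE
  })

#' Construct a MultispectralImage
#'
#' @param data numeric H x W x 6 array in [0, 1], channel order
#'   \code{vis_r, vis_g, vis_b, nir_1, nir_2, nir_3}.
#' @param meta optional list of provenance metadata.
#' @return A \linkS4class{MultispectralImage}.
#' @examples
#' img <- MultispectralImage(array(0.5, c(4, 4, 6)))
#' dim(imgData(img))
#' @export
MultispectralImage <- function(data, meta = list()) {
  new("MultispectralImage", data = data, meta = meta)
}

#' SamplingMask: checkerboard partition of the pixel lattice
#'
#' The pixelated filter array assigns every pixel to exactly one of two
#' filter classes -- visible-pass or NIR-pass -- in a checkerboard layout,
#' so each class samples the scene at half resolution with a one-pixel
#' horizontal offset between the two streams. \code{phase} records the
#' class parity at pixel (1,1): phase 0 puts the visible class on pixels
#' with even (row+col) parity (0-based), phase 1 on odd parity.
#'
#' @slot visMask logical H x W matrix, TRUE at visible-class pixels.
#' @slot nirMask logical H x W matrix, TRUE at NIR-class pixels.
#' @slot phase integer 0 or 1.
#' @exportClass SamplingMask
setClass("SamplingMask",
  representation(visMask = "matrix", nirMask = "matrix", phase = "integer"),
  validity = function(object) {
    v <- object@visMask; n <- object@nirMask
    if (!is.logical(v) || !is.logical(n)) return("masks must be logical")
    if (!identical(dim(v), dim(n))) return("mask dimensions differ")
    if (!(object@phase %in% c(0L, 1L))) return("phase must be 0 or 1")
    if (any(v & n)) return("classes overlap")
    if (!all(v | n)) return("classes do not cover the lattice")
    h <- nrow(v); w <- ncol(v)
    if (h >= 2 && w >= 2) {
      # within every 2x2 block each class appears exactly twice
      blocks <- v[1:(h - 1), 1:(w - 1)] + v[2:h, 1:(w - 1)] +
        v[1:(h - 1), 2:w] + v[2:h, 2:w]
      if (any(blocks != 2L)) return("masks are not a checkerboard")
    }
    TRUE
  })

#' MosaicFrame: raw readout of the hexachromatic sensor
#'
#' Each pixel of the sensor carries one triplet of values read through the
#' three stacked photodiodes; whether the triplet is a visible (R,G,B) or a
#' NIR measurement is decided by the checkerboard filter class of that
#' pixel. The frame therefore holds both half-resolution streams interleaved
#' in a single H x W x 3 array.
#'
#' @slot data numeric H x W x 3 array in [0, 1].
#' @slot phase integer 0 or 1, parity of the visible class (see
#'   \linkS4class{SamplingMask}).
#' @exportClass MosaicFrame
setClass("MosaicFrame",
  representation(data = "array", phase = "integer"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      return("data must be an H x W x 3 array")
    msg <- .checkFinite(d, "data")
    if (!is.null(msg)) return(msg)
    if (!(object@phase %in% c(0L, 1L))) return("phase must be 0 or 1")
    TRUE
  })

#' SparseChannelImage: one half-sampled stream of a mosaic frame
#'
#' Holds the triplet values of a single filter class on its checkerboard
#' support. Unmeasured pixels are stored as 0; the \code{valid} mask is
#' authoritative and a stored 0 at an invalid pixel is never data.
#'
#' @slot data numeric H x W x 3 array; defined exactly where valid.
#' @slot valid logical H x W matrix marking measured pixels.
#' @exportClass SparseChannelImage
setClass("SparseChannelImage",
  representation(data = "array", valid = "matrix"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      return("data must be an H x W x 3 array")
    if (!is.logical(object@valid)) return("valid must be logical")
    if (!identical(dim(d)[1:2], dim(object@valid)))
      return("valid mask dimensions differ from data")
    msg <- .checkFinite(d, "data")
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' InterpolatedImage: a stream with its missing pixels filled in
#'
#' Result of interpolating a \linkS4class{SparseChannelImage}: every pixel
#' is defined, and pixels that were measured pass through unchanged
#' (\code{sourceValid} records which ones those were).
#'
#' @slot data numeric H x W x 3 array, fully defined.
#' @slot sourceValid logical H x W matrix of originally measured pixels.
#' @exportClass InterpolatedImage
setClass("InterpolatedImage",
  representation(data = "array", sourceValid = "matrix"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      return("data must be an H x W x 3 array")
    msg <- .checkFinite(d, "data")
    if (!is.null(msg)) return(msg)
    if (!identical(dim(d)[1:2], dim(object@sourceValid)))
      return("sourceValid dimensions differ from data")
    TRUE
  })

#' SeluParams: scale and shape constants of the SELU activation
#'
#' SELU(x) = lambda * x for x > 0 and lambda * alpha * (exp(x) - 1) for
#' x <= 0. Defaults are the canonical self-normalizing constants.
#'
#' @slot lambda positive scale.
#' @slot alpha positive shape.
#' @exportClass SeluParams
setClass("SeluParams",
  representation(lambda = "numeric", alpha = "numeric"),
  validity = function(object) {
    if (length(object@lambda) != 1L || object@lambda <= 0) return("lambda must be a positive scalar")
    if (length(object@alpha) != 1L || object@alpha <= 0) return("alpha must be a positive scalar")
    TRUE
  })

#' @param lambda positive scale constant.
#' @param alpha positive shape constant.
#' @rdname SeluParams-class
#' @export
seluParams <- function(lambda = 1.0507009873554805, alpha = 1.6732632423543772) {
  new("SeluParams", lambda = lambda, alpha = alpha)
}

#' NetworkConfig: architecture of the residual network
#'
#' @slot depth integer number of layers N (>= 2). Layers 1..N-1 are
#'   convolution + batch normalization + SELU; layer N is a plain
#'   convolution producing the 3-channel residual.
#' @slot filters integer filters per hidden layer (64 in the reference
#'   architecture).
#' @slot kernel integer spatial kernel size (3, with one-pixel padding so
#'   spatial dimensions are preserved).
#' @slot channels integer input/output channel count (3).
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(depth = "integer", filters = "integer",
                 kernel = "integer", channels = "integer"),
  validity = function(object) {
    if (object@depth < 2L) return("depth must be >= 2")
    if (object@filters < 1L) return("filters must be >= 1")
    if (object@kernel != 3L) return("only 3 x 3 kernels are supported")
    if (object@channels < 1L) return("channels must be >= 1")
    TRUE
  })

#' @param depth number of layers (default 20 as in the reference design).
#' @param filters filters per hidden layer.
#' @param channels input/output channels.
#' @rdname NetworkConfig-class
#' @export
networkConfig <- function(depth = 20L, filters = 64L, channels = 3L) {
  new("NetworkConfig", depth = as.integer(depth), filters = as.integer(filters),
      kernel = 3L, channels = as.integer(channels))
}

#' ResidualModel: the learned residual mapping
#'
#' Weights, biases and batch-normalization parameters of the residual
#' network that predicts the high-frequency difference between a bilinearly
#' interpolated stream and the full-resolution truth.
#'
#' @slot layers list of per-layer parameter lists. Hidden layers carry
#'   \code{W} (3 x 3 x in x out), \code{b}, \code{gamma}, \code{beta},
#'   \code{runMean}, \code{runVar}; the final layer carries only
#'   \code{W}, \code{b}.
#' @slot config a \linkS4class{NetworkConfig}.
#' @slot selu a \linkS4class{SeluParams}.
#' @exportClass ResidualModel
setClass("ResidualModel",
  representation(layers = "list", config = "NetworkConfig", selu = "SeluParams"),
  validity = function(object) {
    cfg <- object@config
    if (length(object@layers) != cfg@depth)
      return("number of layers does not match config depth")
    for (n in seq_len(cfg@depth)) {
      ly <- object@layers[[n]]
      cin <- if (n == 1L) cfg@channels else cfg@filters
      cout <- if (n == cfg@depth) cfg@channels else cfg@filters
      if (!identical(dim(ly$W), c(cfg@kernel, cfg@kernel, cin, cout)))
        return(sprintf("layer %d weight shape inconsistent with config", n))
      if (length(ly$b) != cout)
        return(sprintf("layer %d bias length inconsistent with config", n))
      if (n < cfg@depth &&
          (length(ly$gamma) != cout || length(ly$beta) != cout ||
           length(ly$runMean) != cout || length(ly$runVar) != cout))
        return(sprintf("layer %d normalization parameters inconsistent", n))
    }
    TRUE
  })

#' TrainConfig: hyperparameters of the residual-learning optimizer
#'
#' Defaults follow the reference training recipe: Adam with a constant
#' learning rate of 1e-5, MSRA (He) initialization, 100 random 50 x 50
#' patches per image, dihedral augmentation. Batch size and step budget
#' are not prescribed by the recipe and default to desk-scale values.
#'
#' @slot learningRate positive Adam step size.
#' @slot batchSize integer patches per optimization step.
#' @slot steps integer number of optimization steps.
#' @slot depth,filters network architecture (see
#'   \linkS4class{NetworkConfig}).
#' @slot patchSize integer square patch side.
#' @slot patchesPerImage integer random patches extracted per image.
#' @slot augment logical, apply the 8-element dihedral augmentation.
#' @slot seed integer RNG seed controlling init, patching and batching.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 steps = "integer", depth = "integer", filters = "integer",
                 patchSize = "integer", patchesPerImage = "integer",
                 augment = "logical", seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@patchSize < 3L) return("patchSize must be at least the kernel size")
    if (object@batchSize < 1L || object@steps < 1L)
      return("batchSize and steps must be >= 1")
    TRUE
  })

#' @param learningRate Adam learning rate.
#' @param batchSize patches per step.
#' @param steps optimization steps.
#' @param depth,filters architecture.
#' @param patchSize patch side in pixels.
#' @param patchesPerImage random patches per training image.
#' @param augment apply dihedral augmentation.
#' @param seed RNG seed.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(learningRate = 1e-5, batchSize = 64L, steps = 1000L,
                        depth = 20L, filters = 64L, patchSize = 50L,
                        patchesPerImage = 100L, augment = TRUE, seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), steps = as.integer(steps),
      depth = as.integer(depth), filters = as.integer(filters),
      patchSize = as.integer(patchSize),
      patchesPerImage = as.integer(patchesPerImage),
      augment = isTRUE(augment), seed = as.integer(seed))
}

#' MetricReport: the four-metric evaluation of a reconstruction
#'
#' Per-channel PSNR (dB) and MSE for the six channels, plus the
#' 95th-percentile structural dissimilarity (DSSIM, on a 0-1 scale) and the
#' 95th-percentile colour difference (percent of the maximal channel-space
#' distance), each computed separately for the visible and NIR triplets.
#'
#' @slot psnr named numeric(6), dB; \code{Inf} when MSE is exactly 0.
#' @slot mse named numeric(6).
#' @slot dssimP95 named numeric(2) (\code{vis}, \code{nir}) in [0, 1].
#' @slot deltaEP95 named numeric(2) (\code{vis}, \code{nir}), percent.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(psnr = "numeric", mse = "numeric",
                 dssimP95 = "numeric", deltaEP95 = "numeric"),
  validity = function(object) {
    if (length(object@mse) != 6L) return("mse must have 6 entries")
    if (length(object@psnr) != 6L) return("psnr must have 6 entries")
    if (length(object@dssimP95) != 2L || length(object@deltaEP95) != 2L)
      return("dssimP95 and deltaEP95 must have entries for vis and nir")
    ok <- object@mse > 0
    if (any(abs(object@psnr[ok] - 10 * log10(1 / object@mse[ok])) > 1e-9))
      return("psnr and mse are inconsistent (peak 1)")
    if (any(object@dssimP95 < 0 | object@dssimP95 > 1))
      return("dssimP95 must lie in [0, 1]")
    if (any(object@deltaEP95 < 0)) return("deltaEP95 must be >= 0")
    TRUE
  })

#' SceneSpec: parameters of a synthetic hexachromatic scene
#'
#' Describes the content of one generated test scene: sharp step edges and
#' coloured patches in the visible channels, thin bright vessel-like
#' curvilinear structures a few pixels wide in the first NIR channel, a
#' smooth background gradient, a stated degree of correlation between the
#' NIR channels and the visible luminance, and additive Gaussian noise.
#'
#' @slot height,width integer scene size.
#' @slot seed integer RNG seed; identical specs generate identical scenes.
#' @slot nEdges integer number of random step-edge structures.
#' @slot nCurves integer number of thin curvilinear structures.
#' @slot curveWidth numeric curve width in pixels (1-3).
#' @slot gradientAmplitude numeric amplitude of the background ramp.
#' @slot nirCorrelation numeric in [0, 1]; 1 makes every NIR channel equal
#'   the visible luminance, 0 makes NIR content independent.
#' @slot noiseSigma numeric standard deviation of additive Gaussian noise.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(height = "integer", width = "integer", seed = "integer",
                 nEdges = "integer", nCurves = "integer",
                 curveWidth = "numeric", gradientAmplitude = "numeric",
                 nirCorrelation = "numeric", noiseSigma = "numeric"),
  validity = function(object) {
    if (object@height < 2L || object@width < 2L) return("degenerate scene size")
    if (object@curveWidth < 0.5 || object@curveWidth > 3)
      return("curveWidth must lie in [0.5, 3] pixels")
    if (object@nirCorrelation < 0 || object@nirCorrelation > 1)
      return("nirCorrelation must lie in [0, 1]")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@nEdges < 0L || object@nCurves < 0L) return("counts must be >= 0")
    TRUE
  })

#' FrequencyProfile: Fourier-domain comparison of a reconstruction
#'
#' Centered log-magnitude spectra of a reconstruction and its reference,
#' together with the central-column line profile along vertical spatial
#' frequencies (in dB) and their difference. Used to quantify how much
#' high-frequency content a demosaicing method loses.
#'
#' @slot logMagnitude,refLogMagnitude centered log-magnitude spectra (dB).
#' @slot profile,refProfile central-column vertical-frequency profiles (dB).
#' @slot diffProfile \code{profile - refProfile} (dB).
#' @slot freq normalized vertical frequencies (cycles/pixel) of the profile.
#' @exportClass FrequencyProfile
setClass("FrequencyProfile",
  representation(logMagnitude = "matrix", refLogMagnitude = "matrix",
                 profile = "numeric", refProfile = "numeric",
                 diffProfile = "numeric", freq = "numeric"),
  validity = function(object) {
    n <- length(object@freq)
    if (length(object@profile) != n || length(object@refProfile) != n ||
        length(object@diffProfile) != n)
      return("profile lengths inconsistent")
    TRUE
  })
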
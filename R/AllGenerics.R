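#' Extract the pixel array of an image object
#'
#' @param x a \linkS4class{MultispectralImage}, \linkS4class{MosaicFrame},
#'   \linkS4class{SparseChannelImage} or \linkS4class{InterpolatedImage}.
#' @return The underlying numeric array (H x W x C).
#' @examples
#' img <- MultispectralImage(array(0.25, c(4, 4, 6)))
#' range(imgData(img))
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "MultispectralImage", function(x) x@data)
#' @rdname imgData
#' @export
setMethod("imgData", "MosaicFrame", function(x) x@data)
#' @rdname imgData
#' @export
setMethod("imgData", "SparseChannelImage", function(x) x@data)
#' @rdname imgData
#' @export
setMethod("imgData", "InterpolatedImage", function(x) x@data)

#' Channel names of a multispectral image
#' @param x a \linkS4class{MultispectralImage}.
#' @return character(6) channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname channelNames
#' @export
setMethod("channelNames", "MultispectralImage", function(x) CHANNEL_NAMES)

#' Checkerboard phase of a mask or frame
#' @param x a \linkS4class{SamplingMask} or \linkS4class{MosaicFrame}.
#' @return integer 0 or 1, the filter-class parity at the top-left pixel.
#' @export
setGeneric("maskPhase", function(x) standardGeneric("maskPhase"))
#' @rdname maskPhase
#' @export
setMethod("maskPhase", "SamplingMask", function(x) x@phase)
#' @rdname maskPhase
#' @export
setMethod("maskPhase", "MosaicFrame", function(x) x@phase)

#' Class masks of a SamplingMask
#' @param x a \linkS4class{SamplingMask}.
#' @return logical H x W matrix.
#' @export
setGeneric("visMask", function(x) standardGeneric("visMask"))
#' @rdname visMask
#' @export
setMethod("visMask", "SamplingMask", function(x) x@visMask)
#' @rdname visMask
#' @export
setGeneric("nirMask", function(x) standardGeneric("nirMask"))
#' @rdname visMask
#' @export
setMethod("nirMask", "SamplingMask", function(x) x@nirMask)

#' Validity mask of a sparse or interpolated stream
#' @param x a \linkS4class{SparseChannelImage} or
#'   \linkS4class{InterpolatedImage}.
#' @return logical H x W matrix of measured pixels.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname validMask
#' @export
setMethod("validMask", "SparseChannelImage", function(x) x@valid)
#' @rdname validMask
#' @export
setMethod("validMask", "InterpolatedImage", function(x) x@sourceValid)

#' Layer parameters of a residual model
#' @param x a \linkS4class{ResidualModel}.
#' @return list of per-layer parameter lists.
#' @export
setGeneric("modelLayers", function(x) standardGeneric("modelLayers"))
#' @rdname modelLayers
#' @export
setMethod("modelLayers", "ResidualModel", function(x) x@layers)

#' @param x a \linkS4class{ResidualModel}.
#' @param value replacement layer list (shape-checked by class validity).
#' @rdname modelLayers
#' @export
setGeneric("modelLayers<-", function(x, value) standardGeneric("modelLayers<-"))
#' @rdname modelLayers
#' @export
setMethod("modelLayers<-", "ResidualModel", function(x, value) {
  x@layers <- value
  validObject(x)
  x
})

#' Architecture of a residual model
#' @param x a \linkS4class{ResidualModel}.
#' @return the \linkS4class{NetworkConfig}.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname modelConfig
#' @export
setMethod("modelConfig", "ResidualModel", function(x) x@config)

setMethod("show", "MultispectralImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultispectralImage: %d x %d pixels, 6 channels (%s)\n",
              d[1], d[2], paste(CHANNEL_NAMES, collapse = ", ")))
  cat(sprintf("  value range [%.4f, %.4f]\n", min(object@data), max(object@data)))
})

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask: %d x %d checkerboard, phase %d (%d visible / %d NIR pixels)\n",
              nrow(object@visMask), ncol(object@visMask), object@phase,
              sum(object@visMask), sum(object@nirMask)))
})

setMethod("show", "MosaicFrame", function(object) {
  d <- dim(object@data)
  cat(sprintf("MosaicFrame: %d x %d raw sensor frame, phase %d\n",
              d[1], d[2], object@phase))
})

setMethod("show", "SparseChannelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SparseChannelImage: %d x %d, %d/%d pixels measured\n",
              d[1], d[2], sum(object@valid), d[1] * d[2]))
})

setMethod("show", "InterpolatedImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("InterpolatedImage: %d x %d, %d source pixels passed through\n",
              d[1], d[2], sum(object@sourceValid)))
})

setMethod("show", "ResidualModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }, numeric(1)))
  cat(sprintf(
    "ResidualModel: %d layers, %d filters, %d x %d kernels, %d channels (%d parameters)\n",
    cfg@depth, cfg@filters, cfg@kernel, cfg@kernel, cfg@channels, np))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat("  PSNR (dB):", paste(sprintf("%s=%.2f", names(object@psnr), object@psnr),
                            collapse = " "), "\n")
  cat("  MSE:      ", paste(sprintf("%s=%.3g", names(object@mse), object@mse),
                            collapse = " "), "\n")
  cat(sprintf("  p95 DSSIM: vis=%.4f nir=%.4f\n",
              object@dssimP95["vis"], object@dssimP95["nir"]))
  cat(sprintf("  p95 deltaE (%%): vis=%.3f nir=%.3f\n",
              object@deltaEP95["vis"], object@deltaEP95["nir"]))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d, seed %d, %d edges, %d curves (width %.1f px),\n  gradient %.2f, NIR correlation %.2f, noise sigma %.3f\n",
    object@height, object@width, object@seed, object@nEdges, object@nCurves,
    object@curveWidth, object@gradientAmplitude, object@nirCorrelation,
    object@noiseSigma))
})
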
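#' Build the checkerboard sampling masks of the hexachromatic sensor
#'
#' The pixelated filter array alternates visible-pass and NIR-pass filters
#' in a checkerboard, so the two half-resolution streams are offset by one
#' pixel horizontally. With 0-based row/column indices, a pixel belongs to
#' the visible class iff \code{(row + col) %% 2 == phase}.
#'
#' @param height,width positive integers (>= 2).
#' @param phase 0 or 1: the parity of the visible class. Phase 0 places a
#'   visible pixel at the top-left corner.
#' @return A \linkS4class{SamplingMask}.
#' @examples
#' m <- makeSamplingMask(4, 4)
#' sum(visMask(m))  # 8 of 16 pixels are visible-class
#' @export
makeSamplingMask <- function(height, width, phase = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 2L || width < 2L)
    stop("height and width must be integers >= 2")
  phase <- as.integer(phase)
  if (!(phase %in% c(0L, 1L))) stop("phase must be 0 or 1")
  parity <- outer(seq_len(height) - 1L, seq_len(width) - 1L, "+") %% 2L
  vis <- parity == phase
  new("SamplingMask", visMask = vis, nirMask = !vis, phase = phase)
}

#' Simulate the raw sensor readout of a full-resolution scene
#'
#' Applies the checkerboard filter pattern to a 6-channel ground-truth
#' image: visible-class pixels keep their (R,G,B) triplet (channels 1-3),
#' NIR-class pixels keep their NIR triplet (channels 4-6). No other
#' processing (noise, optics) is modelled.
#'
#' @param image a \linkS4class{MultispectralImage}.
#' @param mask a \linkS4class{SamplingMask} of matching size, or a phase
#'   (0/1) from which the mask is built.
#' @return A \linkS4class{MosaicFrame}.
#' @examples
#' img <- MultispectralImage(array(0.5, c(4, 4, 6)))
#' frame <- mosaicImage(img, 0)
#' @export
mosaicImage <- function(image, mask = 0L) {
  stopifnot(is(image, "MultispectralImage"))
  d <- imgData(image)
  h <- dim(d)[1]; w <- dim(d)[2]
  if (!is(mask, "SamplingMask")) mask <- makeSamplingMask(h, w, mask)
  if (!identical(dim(mask@visMask), c(h, w)))
    stop("mask dimensions do not match the image")
  sel <- array(rep(mask@visMask, 3L), c(h, w, 3L))
  out <- ifelse(sel, d[, , 1:3, drop = FALSE], d[, , 4:6, drop = FALSE])
  dim(out) <- c(h, w, 3L)
  new("MosaicFrame", data = out, phase = mask@phase)
}

#' Split a mosaic frame into its visible and NIR half-resolution streams
#'
#' Returns the two \linkS4class{SparseChannelImage} streams whose validity
#' masks are the complementary checkerboard classes. Measured values are
#' copied bit-exactly from the frame; unmeasured positions are stored as 0
#' with the valid mask authoritative.
#'
#' @param frame a \linkS4class{MosaicFrame}.
#' @return A list with elements \code{vis} and \code{nir}.
#' @export
splitFrame <- function(frame) {
  stopifnot(is(frame, "MosaicFrame"))
  d <- imgData(frame)
  h <- dim(d)[1]; w <- dim(d)[2]
  mask <- makeSamplingMask(h, w, frame@phase)
  sel <- array(rep(mask@visMask, 3L), c(h, w, 3L))
  vis <- d; vis[!sel] <- 0
  nir <- d; nir[sel] <- 0
  list(vis = new("SparseChannelImage", data = vis, valid = mask@visMask),
       nir = new("SparseChannelImage", data = nir, valid = mask@nirMask))
}

#' Recombine two complementary streams into a mosaic frame
#'
#' Inverse of \code{\link{splitFrame}}: overlays the measured values of the
#' visible stream and the NIR stream on their checkerboard supports.
#'
#' @param vis,nir complementary \linkS4class{SparseChannelImage} streams.
#' @param phase checkerboard phase of the visible stream.
#' @return A \linkS4class{MosaicFrame}.
#' @export
combineStreams <- function(vis, nir, phase = 0L) {
  stopifnot(is(vis, "SparseChannelImage"), is(nir, "SparseChannelImage"))
  if (any(vis@valid & nir@valid) || !all(vis@valid | nir@valid))
    stop("streams do not partition the pixel lattice")
  h <- dim(vis@data)[1]; w <- dim(vis@data)[2]
  sel <- array(rep(vis@valid, 3L), c(h, w, 3L))
  out <- ifelse(sel, vis@data, nir@data)
  dim(out) <- c(h, w, 3L)
  new("MosaicFrame", data = out, phase = as.integer(phase))
}
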
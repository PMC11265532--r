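#' Fill the missing checkerboard pixels of one stream by 1D bilinear
#' interpolation
#'
#' The baseline demosaicing method: every unmeasured pixel of a
#' half-resolution stream is estimated as the mean of its two horizontally
#' adjacent measured neighbours. Under the checkerboard pattern the
#' horizontal neighbours of a missing pixel are always measured, so the
#' scheme is well defined everywhere; at the left/right image border, where
#' only one horizontal neighbour exists, that neighbour's value is
#' replicated. Measured pixels pass through bit-exactly, so the
#' interpolated image retains the low-frequency content of the eventual
#' full-resolution output.
#'
#' @param sparse a \linkS4class{SparseChannelImage} whose valid mask is one
#'   checkerboard class.
#' @param method \code{"horizontal"} (the 1D baseline) or
#'   \code{"neighbors4"}, a 2D variant averaging the up/down/left/right
#'   measured neighbours, provided for sensitivity comparisons.
#' @return An \linkS4class{InterpolatedImage}.
#' @examples
#' img <- MultispectralImage(array(runif(4 * 6 * 6), c(4, 6, 6)))
#' s <- splitFrame(mosaicImage(img, 0))
#' full <- interpolateStream(s$vis)
#' @export
interpolateStream <- function(sparse, method = c("horizontal", "neighbors4")) {
  stopifnot(is(sparse, "SparseChannelImage"))
  method <- match.arg(method)
  d <- sparse@data
  valid <- sparse@valid
  h <- dim(d)[1]; w <- dim(d)[2]
  if (any(rowSums(valid) == 0L))
    stop("internal error: a row carries no measured pixel")
  acc <- array(0, c(h, w, 3L))
  cnt <- matrix(0, h, w)
  shifts <- list(c(0L, -1L), c(0L, 1L))
  if (method == "neighbors4") shifts <- c(shifts, list(c(-1L, 0L), c(1L, 0L)))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    rDst <- max(1L, 1L - dr):min(h, h - dr)
    cDst <- max(1L, 1L - dc):min(w, w - dc)
    rSrc <- rDst + dr; cSrc <- cDst + dc
    vsrc <- valid[rSrc, cSrc, drop = FALSE]
    acc[rDst, cDst, ] <- acc[rDst, cDst, , drop = FALSE] +
      d[rSrc, cSrc, , drop = FALSE] * array(rep(vsrc, 3L), c(length(rDst), length(cDst), 3L))
    cnt[rDst, cDst] <- cnt[rDst, cDst] + vsrc
  }
  if (any(cnt[!valid] == 0))
    stop("internal error: a missing pixel has no measured neighbour")
  cnt[cnt == 0] <- 1  # avoid 0/0 at measured pixels; overwritten below
  est <- acc / array(rep(cnt, 3L), c(h, w, 3L))
  sel <- array(rep(valid, 3L), c(h, w, 3L))
  out <- ifelse(sel, d, est)
  dim(out) <- c(h, w, 3L)
  new("InterpolatedImage", data = out, sourceValid = valid)
}

#' Demosaic a raw frame with the bilinear baseline
#'
#' Splits the frame into its visible and NIR streams, fills each by
#' \code{\link{interpolateStream}}, and stacks the results into a 6-channel
#' image (visible in channels 1-3, NIR in 4-6).
#'
#' @param frame a \linkS4class{MosaicFrame}.
#' @param method interpolation variant, see \code{\link{interpolateStream}}.
#' @return A \linkS4class{MultispectralImage}.
#' @export
demosaicBilinear <- function(frame, method = "horizontal") {
  streams <- splitFrame(frame)
  vis <- interpolateStream(streams$vis, method)
  nir <- interpolateStream(streams$nir, method)
  h <- dim(vis@data)[1]; w <- dim(vis@data)[2]
  out <- array(0, c(h, w, 6L))
  out[, , 1:3] <- vis@data
  out[, , 4:6] <- nir@data
  MultispectralImage(out, meta = list(method = paste0("bilinear_", method),
                                      phase = frame@phase))
}
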
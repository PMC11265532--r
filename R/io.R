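#' Read and write multispectral images as multi-page TIFF
#'
#' A \linkS4class{MultispectralImage} is stored as a 6-page single-channel
#' TIFF in channel order \code{vis_r, vis_g, vis_b, nir_1, nir_2, nir_3}.
#' Values are quantized to the stored bit depth on write (default 16-bit)
#' and normalized back to [0, 1] on read, so write-then-read is lossless at
#' the stored depth.
#'
#' @param image a \linkS4class{MultispectralImage}.
#' @param path TIFF file path.
#' @param bits bits per sample, 8 or 16.
#' @return \code{writeMultispectralImage}: \code{path} invisibly;
#'   \code{readMultispectralImage}: the image.
#' @export
writeMultispectralImage <- function(image, path, bits = 16L) {
  stopifnot(is(image, "MultispectralImage"), bits %in% c(8L, 16L))
  d <- imgData(image)
  pages <- lapply(1:6, function(cc) d[, , cc])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname writeMultispectralImage
#' @export
readMultispectralImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 6L)
    stop(sprintf("%s: expected a 6-page TIFF, found %d pages", path, length(pages)))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, c(h, w, 6L))
  for (cc in 1:6) {
    pg <- pages[[cc]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grey-stored-as-RGB
    out[, , cc] <- pg
  }
  MultispectralImage(out, meta = list(source = path))
}

#' Read and write mosaic frames (TIFF plus JSON sidecar)
#'
#' The raw frame is a 3-channel TIFF; a sidecar JSON (same path with
#' \code{.json} appended) records the checkerboard phase and the channel
#' semantics so a frame is self-describing.
#'
#' @param frame a \linkS4class{MosaicFrame}.
#' @param path TIFF file path.
#' @param bits bits per sample, 8 or 16.
#' @return \code{writeMosaicFrame}: \code{path} invisibly;
#'   \code{readMosaicFrame}: the frame.
#' @export
writeMosaicFrame <- function(frame, path, bits = 16L) {
  stopifnot(is(frame, "MosaicFrame"))
  tiff::writeTIFF(imgData(frame), path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(
    list(format = "hexdemosaic-mosaic-1", phase = frame@phase,
         semantics = "triplet is visible (R,G,B) where (row+col) parity == phase (0-based), else NIR"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMosaicFrame
#' @param phase checkerboard phase override; by default taken from the
#'   sidecar JSON (error if neither is available).
#' @export
readMosaicFrame <- function(path, phase = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tiff::readTIFF(path)
  if (length(dim(d)) != 3L || dim(d)[3] != 3L)
    stop(path, ": expected a 3-channel TIFF")
  if (is.null(phase)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no sidecar ", sidecar, " and no explicit phase given")
    phase <- jsonlite::read_json(sidecar)$phase
  }
  new("MosaicFrame", data = d, phase = as.integer(phase))
}

#' Read / write a plain 3-channel image file
#'
#' PNG and (single-page) TIFF are supported, selected by extension. Values
#' are normalized to [0, 1] on read (8- or 16-bit) and quantized on write
#' (PNG at 8 bits, TIFF at the requested depth).
#'
#' @param path image file path.
#' @param data H x W x 3 numeric array in [0, 1] (for writing).
#' @param bits bits per sample on write.
#' @return \code{readImageFile}: H x W x 3 array; \code{writeImageFile}:
#'   \code{path} invisibly.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  d <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]
  d
}

#' @rdname readImageFile
#' @export
writeImageFile <- function(data, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(data, path),
    tif = , tiff = tiff::writeTIFF(data, path, bits.per.sample = as.integer(bits)),
    stop("unsupported image format: .", ext))
  invisible(path)
}
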
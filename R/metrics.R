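.asArray <- function(x) {
  if (is(x, "MultispectralImage") || is(x, "MosaicFrame")) return(imgData(x))
  if (is(x, "InterpolatedImage")) return(x@data)
  x
}

.checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shapes")
}

#' Per-channel mean squared error
#'
#' @param a,b numeric arrays of identical shape (H x W or H x W x C), or
#'   image objects.
#' @return Numeric vector, one MSE per channel.
#' @export
channelMSE <- function(a, b) {
  a <- .asArray(a); b <- .asArray(b)
  .checkSameShape(a, b)
  if (is.null(dim(a)) || length(dim(a)) == 2L) return(mean((a - b)^2))
  apply((a - b)^2, length(dim(a)), mean)
}

#' Per-channel peak signal-to-noise ratio
#'
#' \code{psnr = 10 * log10(peak^2 / MSE)} in dB; \code{Inf} when the MSE is
#' exactly zero.
#'
#' @param a,b images of identical shape.
#' @param peak signal peak (1 for unit-scale images).
#' @return Numeric vector of dB values per channel.
#' @export
psnr <- function(a, b, peak = 1) {
  if (peak <= 0) stop("peak must be positive")
  m <- channelMSE(a, b)
  ifelse(m == 0, Inf, 10 * log10(peak^2 / m))
}

# separable Gaussian filtering with symmetric (mirror) boundary handling
.gaussKernel <- function(size = 11L, sigma = 1.5) {
  r <- (seq_len(size) - (size + 1) / 2)
  g <- exp(-r^2 / (2 * sigma^2))
  g / sum(g)
}

.reflectIdx <- function(n, pad) c(pad:1, 1:n, n:(n - pad + 1L))

.gaussFilter <- function(m, g) {
  k <- length(g); pad <- (k - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  if (h < k || w < k) stop("image smaller than the filter window")
  mp <- m[.reflectIdx(h, pad), .reflectIdx(w, pad), drop = FALSE]
  tmp <- matrix(0, h, w + 2L * pad)
  for (i in seq_len(k)) tmp <- tmp + g[i] * mp[i:(i + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(k)) out <- out + g[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out
}

# per-pixel SSIM map of two single-channel matrices; standard constants
# K1 = 0.01, K2 = 0.03 on dynamic range L, 11 x 11 Gaussian window with
# sigma 1.5.
.ssimMap <- function(a, b, L = 1, size = 11L, sigma = 1.5) {
  g <- .gaussKernel(size, sigma)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mu1 <- .gaussFilter(a, g); mu2 <- .gaussFilter(b, g)
  s11 <- .gaussFilter(a * a, g) - mu1^2
  s22 <- .gaussFilter(b * b, g) - mu2^2
  s12 <- .gaussFilter(a * b, g) - mu1 * mu2
  ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
}

#' 95th-percentile structural dissimilarity
#'
#' Computes a per-pixel SSIM map for each channel with the standard 11 x 11
#' Gaussian window (sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range 1),
#' averages the maps across channels, converts to dissimilarity
#' \code{DSSIM = (1 - SSIM) / 2}, and returns its 95th percentile over
#' pixels (a 0-1 scale).
#'
#' @param a,b images of identical shape (H x W or H x W x C).
#' @param probs percentile (default 0.95).
#' @return Scalar DSSIM percentile in [0, 1].
#' @export
dssimP95 <- function(a, b, probs = 0.95) {
  a <- .asArray(a); b <- .asArray(b)
  .checkSameShape(a, b)
  if (length(dim(a)) == 2L) {
    dim(a) <- c(dim(a), 1L); dim(b) <- c(dim(b), 1L)
  }
  nc <- dim(a)[3]
  acc <- matrix(0, dim(a)[1], dim(a)[2])
  for (cc in seq_len(nc)) acc <- acc + .ssimMap(a[, , cc], b[, , cc])
  dssim <- (1 - acc / nc) / 2
  dssim[dssim < 0] <- 0; dssim[dssim > 1] <- 1
  unname(stats::quantile(dssim, probs, type = 7))
}

#' 95th-percentile colour difference
#'
#' Per-pixel Euclidean distance across the three channels, normalized by
#' the maximal possible distance (sqrt(3) * peak) and expressed as a
#' percentage; the 95th percentile over pixels is returned. The same
#' formula applies to the NIR triplet, keeping visible and NIR results
#' comparable. A CIE76 Lab variant (\code{method = "lab"}, visible-domain
#' sRGB only, raw delta-E-ab units) is available for comparison.
#'
#' @param a,b 3-channel images of identical shape.
#' @param probs percentile (default 0.95).
#' @param method \code{"euclidean"} (percent of maximum) or \code{"lab"}.
#' @return Scalar percentile.
#' @export
deltaEP95 <- function(a, b, probs = 0.95, method = c("euclidean", "lab")) {
  method <- match.arg(method)
  a <- .asArray(a); b <- .asArray(b)
  .checkSameShape(a, b)
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop("deltaE requires 3-channel images")
  if (method == "euclidean") {
    d2 <- (a[, , 1] - b[, , 1])^2 + (a[, , 2] - b[, , 2])^2 +
      (a[, , 3] - b[, , 3])^2
    de <- sqrt(d2) / sqrt(3) * 100
  } else {
    toLab <- function(x) {
      m <- cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
      grDevices::convertColor(m, from = "sRGB", to = "Lab")
    }
    la <- toLab(a); lb <- toLab(b)
    de <- sqrt(rowSums((la - lb)^2))
  }
  unname(stats::quantile(de, probs, type = 7))
}

.lumaWeights <- c(0.299, 0.587, 0.114)

#' Luminance of a visible triplet
#'
#' Rec. 601 weighting \code{0.299 R + 0.587 G + 0.114 B}, used for the
#' Fourier-domain analysis of visible reconstructions and as the visible
#' signal that correlated NIR channels track in synthetic scenes.
#'
#' @param x H x W x 3 array (or 6-channel image, of which channels 1-3 are
#'   used).
#' @return H x W matrix.
#' @export
luminance <- function(x) {
  x <- .asArray(x)
  x[, , 1] * .lumaWeights[1] + x[, , 2] * .lumaWeights[2] +
    x[, , 3] * .lumaWeights[3]
}

.fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c((floor(h / 2) + 1L):h, 1:floor(h / 2))
  ci <- c((floor(w / 2) + 1L):w, 1:floor(w / 2))
  m[ri, ci, drop = FALSE]
}

FFT_FLOOR_DB <- -120

#' Fourier-domain comparison of a reconstruction against a reference
#'
#' Computes the centered log-magnitude spectra (dB, floored at -120 dB to
#' guard zeros) of a reconstructed single-channel image and its reference,
#' and extracts the central-column line profile along vertical spatial
#' frequencies together with the reconstruction-minus-reference difference
#' profile. A demosaicing method that suppresses fine detail shows a
#' negative difference at high vertical frequencies.
#'
#' @param recon,reference H x W single-channel matrices (use
#'   \code{\link{luminance}} for visible triplets).
#' @return A \linkS4class{FrequencyProfile}.
#' @export
frequencyCompare <- function(recon, reference) {
  if (!is.matrix(recon) || !is.matrix(reference))
    stop("frequencyCompare expects single-channel matrices")
  .checkSameShape(recon, reference)
  h <- nrow(recon); w <- ncol(recon)
  logMag <- function(m) {
    mag <- Mod(stats::fft(m)) / sqrt(h * w)
    db <- 20 * log10(pmax(mag, 10^(FFT_FLOOR_DB / 20)))
    .fftshift2(db)
  }
  la <- logMag(recon); lb <- logMag(reference)
  centerCol <- floor(w / 2) + 1L
  freq <- (seq_len(h) - 1L - floor(h / 2)) / h
  new("FrequencyProfile", logMagnitude = la, refLogMagnitude = lb,
      profile = la[, centerCol], refProfile = lb[, centerCol],
      diffProfile = la[, centerCol] - lb[, centerCol], freq = freq)
}

#' Mean absolute high-frequency deficit of a frequency profile
#'
#' Summarizes a \linkS4class{FrequencyProfile} by the mean absolute
#' difference (dB) between reconstruction and reference over the highest
#' vertical frequencies -- by default the top quartile of the frequency
#' range, where interpolation losses concentrate.
#'
#' @param fp a \linkS4class{FrequencyProfile}.
#' @param fraction fraction of the frequency range counted as "high"
#'   (default 0.25).
#' @return Scalar mean absolute difference in dB.
#' @export
highFrequencyDeficit <- function(fp, fraction = 0.25) {
  stopifnot(is(fp, "FrequencyProfile"))
  af <- abs(fp@freq)
  sel <- af >= (1 - fraction) * max(af)
  mean(abs(fp@diffProfile[sel]))
}

#' Evaluate a reconstruction with the four-metric protocol
#'
#' Assembles per-channel PSNR and MSE for all six channels, plus the
#' 95th-percentile DSSIM and colour difference for the visible and NIR
#' triplets, into a \linkS4class{MetricReport}.
#'
#' @param recon,truth \linkS4class{MultispectralImage}s (or H x W x 6
#'   arrays) of identical shape.
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateReconstruction <- function(recon, truth) {
  a <- .asArray(recon); b <- .asArray(truth)
  .checkSameShape(a, b)
  if (dim(a)[3] != 6L) stop("evaluation expects 6-channel images")
  m <- channelMSE(a, b)
  names(m) <- CHANNEL_NAMES
  p <- psnr(a, b)
  names(p) <- CHANNEL_NAMES
  new("MetricReport", psnr = p, mse = m,
      dssimP95 = c(vis = dssimP95(a[, , 1:3], b[, , 1:3]),
                   nir = dssimP95(a[, , 4:6], b[, , 4:6])),
      deltaEP95 = c(vis = deltaEP95(a[, , 1:3], b[, , 1:3]),
                    nir = deltaEP95(a[, , 4:6], b[, , 4:6])))
}

#' Serialize a metric report
#'
#' Writes the report as JSON (one object with psnr/mse/dssim_p95/
#' delta_e_p95 blocks) or CSV (metric, channel, value rows).
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output path.
#' @param format \code{"json"} or \code{"csv"} (default from extension).
#' @return \code{path}, invisibly.
#' @export
writeMetricReport <- function(report, path, format = NULL) {
  stopifnot(is(report, "MetricReport"))
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    doc <- list(psnr_db = as.list(report@psnr),
                mse = as.list(report@mse),
                dssim_p95 = as.list(report@dssimP95),
                delta_e_p95_percent = as.list(report@deltaEP95))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(report)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @describeIn writeMetricReport flatten a report to a data frame with
#'   columns metric, channel, value.
#' @param x a \linkS4class{MetricReport}.
#' @param ... unused.
#' @export
as.data.frame.MetricReport <- function(x, ...) {
  data.frame(
    metric = c(rep("psnr_db", 6), rep("mse", 6),
               rep("dssim_p95", 2), rep("delta_e_p95_percent", 2)),
    channel = c(names(x@psnr), names(x@mse),
                names(x@dssimP95), names(x@deltaEP95)),
    value = unname(c(x@psnr, x@mse, x@dssimP95, x@deltaEP95)),
    stringsAsFactors = FALSE)
}
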
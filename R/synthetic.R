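#' Construct a synthetic scene specification
#'
#' Defaults describe the study conditions used throughout the package's
#' tests and experiments: 96 x 96 scenes carrying half a dozen sharp step
#' edges and coloured patches in the visible channels, three thin bright
#' vessel-like curves (2 px wide) in the first NIR channel, a moderate
#' background gradient, NIR channels that track the visible luminance with
#' correlation 0.5, and a small amount of sensor-like Gaussian noise.
#'
#' @param height,width scene size in pixels.
#' @param seed RNG seed; identical specs generate identical scenes.
#' @param nEdges number of step-edge / patch structures.
#' @param nCurves number of thin curvilinear structures.
#' @param curveWidth curve width in pixels (0.5-3).
#' @param gradientAmplitude background ramp amplitude.
#' @param nirCorrelation mixing weight of the visible luminance in the NIR
#'   channels (1 = NIR equals luminance exactly, 0 = independent).
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(height = 96L, width = 96L, seed = 1L, nEdges = 6L,
                      nCurves = 3L, curveWidth = 2, gradientAmplitude = 0.2,
                      nirCorrelation = 0.5, noiseSigma = 0.005) {
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      seed = as.integer(seed), nEdges = as.integer(nEdges),
      nCurves = as.integer(nCurves), curveWidth = as.numeric(curveWidth),
      gradientAmplitude = as.numeric(gradientAmplitude),
      nirCorrelation = as.numeric(nirCorrelation),
      noiseSigma = as.numeric(noiseSigma))
}

# random half-plane step: adds a per-channel offset on one side of a line
.addStep <- function(img, h, w, amp = 0.35) {
  theta <- stats::runif(1, 0, 2 * pi)
  px <- stats::runif(1, 1, w); py <- stats::runif(1, 1, h)
  delta <- stats::runif(dim(img)[3], -amp, amp)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  side <- (cos(theta) * (xs - px) + sin(theta) * (ys - py)) > 0
  for (cc in seq_len(dim(img)[3]))
    img[, , cc] <- img[, , cc] + side * delta[cc]
  img
}

# random axis-aligned rectangle with a constant per-channel colour shift
.addRect <- function(img, h, w, amp = 0.3) {
  r1 <- sample.int(h, 1L); r2 <- sample.int(h, 1L)
  c1 <- sample.int(w, 1L); c2 <- sample.int(w, 1L)
  rr <- sort(c(r1, r2)); cr <- sort(c(c1, c2))
  delta <- stats::runif(dim(img)[3], -amp, amp)
  for (cc in seq_len(dim(img)[3]))
    img[rr[1]:rr[2], cr[1]:cr[2], cc] <- img[rr[1]:rr[2], cr[1]:cr[2], cc] + delta[cc]
  img
}

# anti-aliased random-walk polyline of given width; returns the stamped
# intensity map and the sampled path
.drawCurve <- function(h, w, width, amp = 0.8) {
  map <- matrix(0, h, w)
  x <- stats::runif(1, 5, w - 4); y <- stats::runif(1, 5, h - 4)
  ang <- stats::runif(1, 0, 2 * pi)
  nSteps <- round(1.2 * max(h, w))
  sigma <- width / 2
  half <- max(1L, ceiling(2 * sigma))
  pts <- matrix(NA_real_, nSteps, 2L)
  for (s in seq_len(nSteps)) {
    ang <- ang + stats::rnorm(1, sd = 0.25)
    x <- x + 0.75 * cos(ang); y <- y + 0.75 * sin(ang)
    if (x < 2 || x > w - 1 || y < 2 || y > h - 1) {
      ang <- ang + pi / 2
      x <- min(max(x, 2), w - 1); y <- min(max(y, 2), h - 1)
    }
    pts[s, ] <- c(y, x)
    # Gaussian cross-section stamp around the continuous path point
    ri <- max(1L, floor(y) - half):min(h, ceiling(y) + half)
    ci <- max(1L, floor(x) - half):min(w, ceiling(x) + half)
    d2 <- outer((ri - y)^2, (ci - x)^2, "+")
    map[ri, ci] <- pmax(map[ri, ci], amp * exp(-d2 / (2 * sigma^2)))
  }
  list(map = map, points = pts)
}

#' Generate a synthetic 6-channel ground-truth scene
#'
#' Builds a deterministic scene from a \linkS4class{SceneSpec}: visible
#' channels get per-channel base levels, a smooth oriented background
#' gradient, random half-plane step edges and coloured rectangles; the NIR
#' channels mix the visible luminance (weight \code{nirCorrelation}) with
#' independent NIR content (weight \code{1 - nirCorrelation}) that carries
#' its own smooth structure plus, in the first NIR channel, thin bright
#' anti-aliased random-walk curves mimicking fluorescent lymphatic
#' vessels a few pixels wide. Gaussian noise is added last and everything
#' is clipped to [0, 1].
#'
#' The placed structures are recorded in the image metadata
#' (\code{meta(scene)$structures}) for structural assertions.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A \linkS4class{MultispectralImage}.
#' @examples
#' sc <- generateScene(sceneSpec(seed = 7))
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  h <- spec@height; w <- spec@width
  withLocalSeed(spec@seed, {
    xs <- matrix(rep(seq_len(w), each = h), h, w) / w
    ys <- matrix(rep(seq_len(h), w), h, w) / h
    ramp <- function() {
      th <- stats::runif(1, 0, 2 * pi)
      r <- cos(th) * xs + sin(th) * ys
      spec@gradientAmplitude * (r - min(r)) / max(max(r) - min(r), 1e-12)
    }
    vis <- array(0, c(h, w, 3L))
    for (cc in 1:3) vis[, , cc] <- stats::runif(1, 0.25, 0.6) + ramp()
    edges <- list()
    if (spec@nEdges > 0L) for (k in seq_len(spec@nEdges)) {
      if (k %% 2L == 1L) vis <- .addStep(vis, h, w) else vis <- .addRect(vis, h, w)
    }
    vis[vis < 0] <- 0; vis[vis > 1] <- 1
    luma <- luminance(vis)
    indep <- array(0, c(h, w, 3L))
    for (cc in 1:3) indep[, , cc] <- stats::runif(1, 0.1, 0.5) + ramp()
    if (spec@nEdges > 0L) for (k in seq_len(max(1L, spec@nEdges %/% 2L)))
      indep <- .addStep(indep, h, w, amp = 0.25)
    curves <- list()
    if (spec@nCurves > 0L) for (k in seq_len(spec@nCurves)) {
      cv <- .drawCurve(h, w, spec@curveWidth)
      indep[, , 1] <- indep[, , 1] + cv$map
      curves[[k]] <- cv$points
    }
    indep[indep < 0] <- 0; indep[indep > 1] <- 1
    rho <- spec@nirCorrelation
    nir <- array(0, c(h, w, 3L))
    for (cc in 1:3) nir[, , cc] <- rho * luma + (1 - rho) * indep[, , cc]
    out <- array(0, c(h, w, 6L))
    out[, , 1:3] <- vis
    out[, , 4:6] <- nir
    if (spec@noiseSigma > 0)
      out <- out + array(stats::rnorm(length(out), sd = spec@noiseSigma), dim(out))
    out[out < 0] <- 0; out[out > 1] <- 1
    MultispectralImage(out, meta = list(spec = as.list.SceneSpec(spec),
                                        structures = list(curves = curves)))
  })
}

# plain-list form of a SceneSpec, used for manifests
as.list.SceneSpec <- function(x, ...) {
  list(height = x@height, width = x@width, seed = x@seed, nEdges = x@nEdges,
       nCurves = x@nCurves, curveWidth = x@curveWidth,
       gradientAmplitude = x@gradientAmplitude,
       nirCorrelation = x@nirCorrelation, noiseSigma = x@noiseSigma)
}

.specFromList <- function(l) {
  sceneSpec(height = l$height, width = l$width, seed = l$seed,
            nEdges = l$nEdges, nCurves = l$nCurves, curveWidth = l$curveWidth,
            gradientAmplitude = l$gradientAmplitude,
            nirCorrelation = l$nirCorrelation, noiseSigma = l$noiseSigma)
}

#' Generate a reproducible set of synthetic scenes
#'
#' Scene \code{i} uses seed \code{baseSeed + i}; the returned manifest
#' records every scene's full specification so the set can be regenerated
#' bit-identically (see \code{\link{generateFromManifest}}).
#'
#' @param n number of scenes (>= 1).
#' @param baseSeed base RNG seed.
#' @param template a \linkS4class{SceneSpec} providing all non-seed
#'   parameters.
#' @return List with \code{scenes} (list of
#'   \linkS4class{MultispectralImage}) and \code{manifest} (list of spec
#'   lists).
#' @export
generateSceneDataset <- function(n, baseSeed = 1L, template = sceneSpec()) {
  if (n < 1L) stop("n must be >= 1")
  manifest <- lapply(seq_len(n), function(i) {
    l <- as.list.SceneSpec(template)
    l$seed <- as.integer(baseSeed + i)
    l
  })
  list(scenes = lapply(manifest, function(l) generateScene(.specFromList(l))),
       manifest = manifest)
}

#' Regenerate scenes from a manifest
#'
#' @param manifest a manifest as produced by
#'   \code{\link{generateSceneDataset}} (or read back from JSON).
#' @return List of \linkS4class{MultispectralImage}.
#' @export
generateFromManifest <- function(manifest) {
  lapply(manifest, function(l) generateScene(.specFromList(l)))
}

#' Write / read a scene manifest as JSON
#'
#' @param manifest manifest list.
#' @param path JSON file path.
#' @return \code{writeSceneManifest}: \code{path} invisibly;
#'   \code{readSceneManifest}: the manifest list.
#' @export
writeSceneManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSceneManifest
#' @export
readSceneManifest <- function(path) {
  jsonlite::read_json(path)
}
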
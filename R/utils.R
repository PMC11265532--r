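#' Evaluate an expression under a local, pinned RNG state
#'
#' Sets the seed with an explicitly pinned generator
#' (Mersenne-Twister / Inversion / Rejection) so results are reproducible
#' across platforms and R versions, and restores the caller's RNG state
#' afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# simple stderr logger with timestamps
.logMsg <- function(level, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
}

# replicate a logical/numeric H x W matrix across c channels
.rep3 <- function(m, channels = 3L) {
  array(rep(m, channels), c(dim(m), channels))
}
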
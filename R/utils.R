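# Internal helpers shared across modules: angle arithmetic on the circle,
# seeded evaluation that does not disturb the caller's RNG stream.

degToRad <- function(deg) deg * pi / 180
radToDeg <- function(rad) rad * 180 / pi

#' Wrap angles into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into [0, 360).
#' @export
wrapDeg <- function(deg) {
  out <- deg %% 360
  out[out == 360] <- 0
  out
}

# circular distance in degrees, in [0, 180]
circDistDeg <- function(a, b) {
  d <- abs(wrapDeg(a) - wrapDeg(b)) %% 360
  pmin(d, 360 - d)
}

# signed smallest rotation taking `from` to `to`, in (-180, 180]
circDiffDeg <- function(to, from) {
  d <- (to - from) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Evaluate expr with a fixed RNG state, restoring the caller's stream after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a per-view seed from a base seed and an angle; stays below 2^31.
viewSeed <- function(base, angleDeg) {
  (as.integer(base) %% 1000003L) * 1000L + (as.integer(round(wrapDeg(angleDeg))) %% 360L)
}

# max-projection of a 3D array [x, y, z] along y without apply() overhead
mipAlongY <- function(stack) {
  d <- dim(stack)
  out <- stack[, 1L, ]
  if (d[2L] > 1L) for (j in 2:d[2L]) out <- pmax(out, stack[, j, ])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
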
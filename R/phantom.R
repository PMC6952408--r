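# Embryo-like phantom: point emitters in an ellipsoidal shell with an
# azimuthally modulated density and optional obstruction sectors.

# relative azimuthal density (dimensionless, 1 = base)
relDensity <- function(phiDeg, amplitude, phaseDeg, order) {
  out <- rep(1, length(phiDeg))
  for (m in seq_along(amplitude))
    out <- out + amplitude[m] * cos(degToRad(order[m] * (phiDeg - phaseDeg[m])))
  out
}

shellVolume <- function(radii, thickness) {
  inner <- pmax(radii - thickness, 0)
  4 / 3 * pi * (prod(radii) - prod(inner))
}

#' Generate an embryo-like emitter phantom
#'
#' Draws fluorophore emitters as an inhomogeneous Poisson point process on an
#' ellipsoidal shell: uniform candidates in the shell are thinned by the
#' azimuthal density density(phi) = base * (1 + sum_m a_m cos(order_m *
#' (phi - phase_m))), phi measured in the x-z plane from +x. Identical seed
#' and parameters reproduce the emitter list bit-exactly.
#'
#' @param shellRadii ellipsoid radii (x, y, z) in micrometres.
#' @param shellThickness shell thickness in micrometres.
#' @param shellCenter ellipsoid centre (um), default the rotation axis origin.
#' @param baseDensity base emitter density per cubic micrometre.
#' @param modAmplitude,modPhaseDeg,modOrder azimuthal modulation terms; the
#'   density must stay non-negative at every azimuth.
#' @param yBandFraction emitters are kept only within this fraction of the y
#'   radius around the equator (default 0.75): embryos are elongated, open
#'   structures, and a closed shell would place always-accessible polar caps
#'   on the rotation axis that no real sample has.
#' @param obstructions data.frame with columns \code{phi1}, \code{phi2}
#'   (degrees), \code{r1}, \code{r2} (um) and \code{extra} (attenuation per
#'   um) describing absorbing sectors (pigment, dense tissue).
#' @param attenuationBase extra attenuation per um inside the sample mask on
#'   top of the nominal tissue attenuation in \code{\link{spimOptics}}.
#' @param intensity emitter brightness in photons (scalar, recycled).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a \linkS4class{Phantom}.
#' @examples
#' ph <- makePhantom(seed = 1)
#' ph
#' @export
makePhantom <- function(shellRadii = c(130, 160, 130), shellThickness = 30,
                        shellCenter = c(0, 0, 0), baseDensity = 1e-3,
                        modAmplitude = numeric(), modPhaseDeg = numeric(),
                        modOrder = rep(1, length(modAmplitude)),
                        yBandFraction = 0.75,
                        obstructions = emptyObstructions(),
                        attenuationBase = 0, intensity = 3000, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(modAmplitude) == length(modPhaseDeg),
            length(modAmplitude) == length(modOrder))
  phiGrid <- seq(0, 359.75, by = 0.25)
  dens <- relDensity(phiGrid, modAmplitude, modPhaseDeg, modOrder)
  if (any(dens < 0))
    stop(sprintf("density is negative at phi = %.2f deg (%.4f); reduce modulation amplitudes",
                 phiGrid[which.min(dens)], min(dens)))
  maxRel <- max(dens)
  vol <- shellVolume(shellRadii, shellThickness)
  inner <- pmax(shellRadii - shellThickness, 0)
  pos <- withSeed(as.integer(seed), {
    n0 <- stats::rpois(1L, baseDensity * maxRel * vol)   # homogeneous envelope
    acc <- matrix(numeric(0), 0, 3)
    while (nrow(acc) < n0) {
      m <- max(1000L, 2L * (n0 - nrow(acc)))
      cand <- cbind(stats::runif(m, -shellRadii[1], shellRadii[1]),
                    stats::runif(m, -shellRadii[2], shellRadii[2]),
                    stats::runif(m, -shellRadii[3], shellRadii[3]))
      q <- (cand[, 1] / shellRadii[1])^2 + (cand[, 2] / shellRadii[2])^2 +
        (cand[, 3] / shellRadii[3])^2
      qi <- if (all(inner > 0))
        (cand[, 1] / inner[1])^2 + (cand[, 2] / inner[2])^2 + (cand[, 3] / inner[3])^2
      else rep(2, m)
      keep <- q <= 1 & qi > 1 & abs(cand[, 2]) <= yBandFraction * shellRadii[2]
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    acc <- acc[seq_len(n0), , drop = FALSE]
    # thin to the requested azimuthal density
    phi <- wrapDeg(radToDeg(atan2(acc[, 3], acc[, 1])))
    keep <- stats::runif(n0) < relDensity(phi, modAmplitude, modPhaseDeg, modOrder) / maxRel
    acc[keep, , drop = FALSE]
  })
  pos <- sweep(pos, 2, shellCenter, `+`)
  new("Phantom", emitters = pos, intensity = rep(intensity, nrow(pos)),
      shellCenter = shellCenter, shellRadii = shellRadii,
      shellThickness = shellThickness, densityBase = baseDensity,
      densityAmplitude = as.numeric(modAmplitude),
      densityPhaseDeg = as.numeric(modPhaseDeg),
      densityOrder = as.numeric(modOrder),
      obstructions = obstructions, attenuationBase = attenuationBase,
      seed = as.integer(seed))
}

#' @rdname makePhantom
#' @export
emptyObstructions <- function() {
  data.frame(phi1 = numeric(), phi2 = numeric(), r1 = numeric(),
             r2 = numeric(), extra = numeric())
}

#' Rotate a phantom about the rotation axis
#'
#' Rotates emitter positions, the density modulation phases and the
#' obstruction sectors by \code{deg} about +y (positive = increasing azimuth).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param deg rotation in degrees.
#' @return the rotated \linkS4class{Phantom}.
#' @export
rotatePhantom <- function(phantom, deg) {
  a <- degToRad(deg)
  e <- phantom@emitters
  x <- e[, 1] * cos(a) - e[, 3] * sin(a)
  z <- e[, 1] * sin(a) + e[, 3] * cos(a)
  phantom@emitters <- cbind(x, e[, 2], z)
  colnames(phantom@emitters) <- NULL
  phantom@densityPhaseDeg <- wrapDeg(phantom@densityPhaseDeg + deg)
  if (nrow(phantom@obstructions)) {
    phantom@obstructions$phi1 <- wrapDeg(phantom@obstructions$phi1 + deg)
    phantom@obstructions$phi2 <- wrapDeg(phantom@obstructions$phi2 + deg)
  }
  phantom
}

#' Default simulated SPIM optics
#'
#' Attenuation lengths are set so that, at the default emitter brightness,
#' signal stays detectably above the read noise out to a combined
#' illumination + detection in-sample path of roughly 150-250 um and is lost
#' beyond that -- the useful-depth regime of a few hundred micrometres known
#' for SPIM in semi-transparent embryos; the PSF widens linearly with the
#' in-sample path. The default 128^3 stack at 3 um pitch covers a 384 um
#' field of view around a ~260 um embryo.
#'
#' @param lIll,lDet attenuation lengths (um), default 30.
#' @param sigma0 PSF sigma at zero depth (um), default 4.
#' @param blurRate sigma growth per um of in-sample path, default 0.02.
#' @param pitch voxel pitch (um), default 3.
#' @param stackDim stack shape in voxels, default c(128, 128, 128).
#' @param readNoise read-noise sigma in counts, default 2.
#' @param photonScale counts per photon, default 1.
#' @param noiseSeed base seed for the noise streams.
#' @return an \linkS4class{OpticsConfig}.
#' @export
spimOptics <- function(lIll = 30, lDet = 30, sigma0 = 4, blurRate = 0.02,
                       pitch = 3, stackDim = c(128L, 128L, 128L),
                       readNoise = 2, photonScale = 1, noiseSeed = 1L) {
  new("OpticsConfig", lIll = lIll, lDet = lDet, sigma0 = sigma0,
      blurRate = blurRate, pitch = pitch, stackDim = as.integer(stackDim),
      readNoise = readNoise, photonScale = photonScale,
      noiseSeed = as.integer(noiseSeed))
}
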
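# Simulated SPIM acquisition: Beer-Lambert attenuation along the straight
# illumination ray (+x) and detection path (+z), a Gaussian PSF whose sigma
# grows with the summed in-sample path, then Poisson shot noise and Gaussian
# read noise. The sample rotates about +y; a view at stage angle theta sees
# the emitters rotated by -theta.

# half-open azimuthal sector membership with wrap-around
inSector <- function(phiDeg, phi1, phi2) {
  phi <- wrapDeg(phiDeg); a <- wrapDeg(phi1); b <- wrapDeg(phi2)
  if (a <= b) phi >= a & phi < b else phi >= a | phi < b
}

# attenuation coefficient (per um) at camera-frame points (x, y, z) for a
# phantom viewed at `angleDeg`; base tissue term 1/lIll plus phantom extras.
attenCoef <- function(x, y, z, phantom, optics, angleDeg) {
  a <- degToRad(angleDeg)
  xs <- x * cos(a) - z * sin(a)          # back to the sample frame
  zs <- x * sin(a) + z * cos(a)
  cc <- phantom@shellCenter; rr <- phantom@shellRadii
  inside <- ((xs - cc[1]) / rr[1])^2 + ((y - cc[2]) / rr[2])^2 +
    ((zs - cc[3]) / rr[3])^2 <= 1
  mu <- inside * (1 / optics@lIll + phantom@attenuationBase)
  ob <- phantom@obstructions
  if (nrow(ob)) {
    phi <- wrapDeg(radToDeg(atan2(zs, xs)))
    r <- sqrt(xs^2 + zs^2)
    for (k in seq_len(nrow(ob)))
      mu <- mu + ob$extra[k] *
        (inSector(phi, ob$phi1[k], ob$phi2[k]) & r >= ob$r1[k] & r < ob$r2[k])
  }
  mu
}

# in-sample indicator at camera-frame points (geometric path bookkeeping)
insideSample <- function(x, y, z, phantom, angleDeg) {
  a <- degToRad(angleDeg)
  xs <- x * cos(a) - z * sin(a)
  zs <- x * sin(a) + z * cos(a)
  cc <- phantom@shellCenter; rr <- phantom@shellRadii
  ((xs - cc[1]) / rr[1])^2 + ((y - cc[2]) / rr[2])^2 + ((zs - cc[3]) / rr[3])^2 <= 1
}

# Per-emitter degradation at one view angle: attenuation factors, in-sample
# path lengths and PSF sigma. Positions returned in the camera frame (um).
emitterResponse <- function(phantom, optics, angleDeg) {
  a <- degToRad(-angleDeg)               # stage rotation: sample by -theta
  e <- phantom@emitters
  x <- e[, 1] * cos(a) - e[, 3] * sin(a)
  y <- e[, 2]
  z <- e[, 1] * sin(a) + e[, 3] * cos(a)
  n <- length(x)
  pitch <- optics@pitch; d <- optics@stackDim
  half <- d * pitch / 2
  illInt <- pathIll <- pathDet <- numeric(n)
  # illumination: march +x from the stack border to each emitter
  xg <- seq(-half[1] + pitch / 2, half[1] - pitch / 2, by = pitch)
  for (xc in xg) {
    m <- x > xc
    if (!any(m)) next
    mu <- attenCoef(rep(xc, sum(m)), y[m], z[m], phantom, optics, angleDeg)
    illInt[m] <- illInt[m] + mu * pitch
    pathIll[m] <- pathIll[m] +
      insideSample(rep(xc, sum(m)), y[m], z[m], phantom, angleDeg) * pitch
  }
  # detection: march +z from each emitter to the stack border
  zg <- seq(-half[3] + pitch / 2, half[3] - pitch / 2, by = pitch)
  for (zc in zg) {
    m <- z < zc
    if (!any(m)) next
    pathDet[m] <- pathDet[m] +
      insideSample(x[m], y[m], rep(zc, sum(m)), phantom, angleDeg) * pitch
  }
  attIll <- exp(-illInt)
  attDet <- exp(-pathDet / optics@lDet)
  sigma <- optics@sigma0 + optics@blurRate * (pathIll + pathDet)
  data.frame(x = x, y = y, z = z, attIll = attIll, attDet = attDet,
             att = attIll * attDet, pathIll = pathIll, pathDet = pathDet,
             sigma = sigma)
}

# Render emitters as normalised Gaussian blobs at sub-voxel positions.
renderStack <- function(resp, intensity, optics) {
  d <- optics@stackDim; pitch <- optics@pitch
  stack <- array(0, d)
  vx <- resp$x / pitch + (d[1] + 1) / 2
  vy <- resp$y / pitch + (d[2] + 1) / 2
  vz <- resp$z / pitch + (d[3] + 1) / 2
  inField <- vx >= 1 & vx <= d[1] & vy >= 1 & vy <= d[2] & vz >= 1 & vz <= d[3]
  nClipped <- sum(!inField)
  amp <- intensity * resp$att
  for (i in which(inField)) {
    sv <- resp$sigma[i] / pitch
    w <- max(2L, as.integer(ceiling(3.5 * sv)))
    ix <- max(1L, floor(vx[i]) - w):min(d[1], floor(vx[i]) + w + 1L)
    iy <- max(1L, floor(vy[i]) - w):min(d[2], floor(vy[i]) + w + 1L)
    iz <- max(1L, floor(vz[i]) - w):min(d[3], floor(vz[i]) + w + 1L)
    gx <- exp(-(ix - vx[i])^2 / (2 * sv^2))
    gy <- exp(-(iy - vy[i])^2 / (2 * sv^2))
    gz <- exp(-(iz - vz[i])^2 / (2 * sv^2))
    blob <- outer(outer(gx, gy), gz)
    stack[ix, iy, iz] <- stack[ix, iy, iz] + amp[i] * blob / sum(blob)
  }
  attr(stack, "clipped") <- nClipped
  stack
}

#' Simulate one SPIM view of a phantom
#'
#' Rotates the emitters by minus the stage angle about +y and renders them
#' with (i) Beer-Lambert illumination attenuation integrated along the
#' straight +x ray from the stack border (tissue term plus obstruction
#' extras), (ii) detection attenuation exp(-depth / lDet) along +z, (iii) a
#' normalised Gaussian point-spread function with sigma = sigma0 + blurRate *
#' (illumination + detection in-sample path), and (iv) optional Poisson shot
#' noise followed by additive Gaussian read noise. Deterministic for fixed
#' phantom, optics, angle and seeds. Emitters falling outside the stack are
#' clipped and counted (attribute \code{clipped} of the stack).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param angleDeg rotation-stage angle in degrees.
#' @param noise apply the Poisson + Gaussian noise model (default TRUE).
#' @return a \linkS4class{SpimView} in camera counts.
#' @export
acquireView <- function(phantom, optics, angleDeg, noise = TRUE) {
  resp <- emitterResponse(phantom, optics, angleDeg)
  stack <- renderStack(resp, phantom@intensity, optics)
  clipped <- attr(stack, "clipped")
  if (clipped > 0)
    message(sprintf("acquireView: %d emitter(s) clipped outside the stack at %.1f deg",
                    clipped, angleDeg))
  if (noise) {
    stack <- withSeed(viewSeed(optics@noiseSeed, angleDeg), {
      counts <- optics@photonScale * stats::rpois(length(stack), stack)
      counts + stats::rnorm(length(counts), 0, optics@readNoise)
    })
    stack[stack < 0] <- 0
    dim(stack) <- optics@stackDim
  } else {
    stack <- stack * optics@photonScale
    attr(stack, "clipped") <- NULL
  }
  new("SpimView", angle = wrapDeg(angleDeg), stack = stack, pitch = optics@pitch,
      provenance = sprintf("phantom seed %d, angle %.1f", phantom@seed, angleDeg))
}

#' Simulate a blank (sample-free) view
#'
#' Noise-only stack used to calibrate the background entropy level: the
#' entropy scale is condition-dependent, so the blank must share the noise
#' model of the data it calibrates.
#'
#' @inheritParams acquireView
#' @return a \linkS4class{SpimView} containing only noise.
#' @export
acquireBlank <- function(optics) {
  stack <- withSeed(viewSeed(optics@noiseSeed, 359.9) + 7L, {
    n <- prod(optics@stackDim)
    v <- stats::rnorm(n, 0, optics@readNoise)
    v[v < 0] <- 0
    array(v, optics@stackDim)
  })
  new("SpimView", angle = 0, stack = stack, pitch = optics@pitch,
      provenance = "blank")
}

#' Ground-truth coverage of a phantom over a set of view angles
#'
#' For each 10-degree azimuthal bin of the phantom (sample frame) and each
#' view angle, counts the emitters that are "well imaged": combined
#' attenuation factor at or above \code{attThreshold} and PSF sigma at or
#' below \code{sigmaFactor * sigma0}. Computed from the noiseless
#' attenuation and blur fields, independent of the image-based metric, and
#' used as the oracle in simulation studies.
#'
#' @inheritParams acquireView
#' @param angles view angles in degrees.
#' @param binWidth azimuthal bin width in degrees (default 10).
#' @param attThreshold minimal combined attenuation factor (default 0.5).
#' @param sigmaFactor maximal sigma as a multiple of sigma0 (default 2).
#' @return data.frame with columns \code{bin_start_deg}, \code{view_angle_deg},
#'   \code{well_imaged}, \code{total}.
#' @export
groundTruthCoverage <- function(phantom, optics, angles, binWidth = 10,
                                attThreshold = 0.5, sigmaFactor = 2) {
  e <- phantom@emitters
  phi <- wrapDeg(radToDeg(atan2(e[, 3], e[, 1])))
  binStart <- floor(phi / binWidth) * binWidth
  starts <- seq(0, 360 - binWidth, by = binWidth)
  total <- as.integer(table(factor(binStart, levels = starts)))
  if (length(angles) == 0L)
    return(data.frame(bin_start_deg = numeric(), view_angle_deg = numeric(),
                      well_imaged = integer(), total = integer()))
  out <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    resp <- emitterResponse(phantom, optics, angles[i])
    good <- resp$att >= attThreshold & resp$sigma <= sigmaFactor * optics@sigma0
    wi <- as.integer(table(factor(binStart[good], levels = starts)))
    out[[i]] <- data.frame(bin_start_deg = starts, view_angle_deg = angles[i],
                           well_imaged = wi, total = total)
  }
  do.call(rbind, out)
}

#' Simulate a full multi-view acquisition
#'
#' One view per angle plus the noiseless ground-truth coverage table.
#'
#' @inheritParams groundTruthCoverage
#' @param noise apply the noise model (default TRUE).
#' @return list with \code{views} (list of \linkS4class{SpimView}) and
#'   \code{groundTruth} (see \code{\link{groundTruthCoverage}}).
#' @export
acquireMultiView <- function(phantom, optics, angles, noise = TRUE,
                             binWidth = 10) {
  if (anyDuplicated(wrapDeg(angles)))
    stop("view angles must be distinct modulo 360")
  if (length(angles) == 0L)
    return(list(views = list(),
                groundTruth = groundTruthCoverage(phantom, optics, numeric(0), binWidth)))
  views <- lapply(angles, function(a) acquireView(phantom, optics, a, noise = noise))
  gt <- groundTruthCoverage(phantom, optics, angles, binWidth)
  list(views = views, groundTruth = gt)
}
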
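#' @import methods
NULL

#' Ground-truth phantom for the multi-view SPIM simulator
#'
#' A \code{Phantom} is a cloud of point fluorophore emitters distributed in an
#' ellipsoidal shell (an embryo-like geometry: labelled nuclei concentrated in
#' a surface layer), with an angularly inhomogeneous density over azimuth and
#' optional optical obstructions (azimuthal sectors with extra attenuation,
#' emulating pigment or dense tissue).
#'
#' @slot emitters numeric matrix (n x 3), emitter positions in micrometres
#'   relative to the rotation axis; columns x, y, z.
#' @slot intensity numeric vector of emitter brightness in photons.
#' @slot shellCenter,shellRadii numeric length-3, ellipsoid centre and radii (um).
#' @slot shellThickness shell thickness (um); emitters lie between the outer
#'   ellipsoid and the concentric inner ellipsoid with radii reduced by it.
#' @slot densityBase base emitter density per cubic micrometre.
#' @slot densityAmplitude,densityPhaseDeg,densityOrder parameters of the
#'   azimuthal density modulation density(phi) = base * (1 + sum_m a_m *
#'   cos(order_m * (phi - phase_m))).
#' @slot obstructions data.frame with columns \code{phi1}, \code{phi2}
#'   (degrees, half-open sector), \code{r1}, \code{r2} (radial interval, um)
#'   and \code{extra} (additional attenuation coefficient per um).
#' @slot attenuationBase extra attenuation coefficient per um inside the
#'   sample mask, on top of the nominal tissue attenuation of the optics.
#' @slot seed integer seed that generated the emitter cloud.
#' @export
setClass("Phantom", representation(
  emitters = "matrix", intensity = "numeric",
  shellCenter = "numeric", shellRadii = "numeric", shellThickness = "numeric",
  densityBase = "numeric", densityAmplitude = "numeric",
  densityPhaseDeg = "numeric", densityOrder = "numeric",
  obstructions = "data.frame", attenuationBase = "numeric", seed = "integer"))

setValidity("Phantom", function(object) {
  msg <- character()
  if (ncol(object@emitters) != 3L) msg <- c(msg, "emitters must be an n x 3 matrix")
  if (length(object@intensity) != nrow(object@emitters))
    msg <- c(msg, "one intensity per emitter required")
  if (any(object@intensity < 0)) msg <- c(msg, "emitter intensities must be >= 0")
  if (length(object@shellRadii) != 3L || any(object@shellRadii <= 0))
    msg <- c(msg, "shellRadii must be 3 positive numbers")
  if (object@shellThickness <= 0) msg <- c(msg, "shellThickness must be > 0")
  if (object@attenuationBase < 0) msg <- c(msg, "attenuationBase must be >= 0")
  if (nrow(object@obstructions) > 0 && any(object@obstructions$extra < 0))
    msg <- c(msg, "obstruction attenuation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Optical configuration of the simulated SPIM
#'
#' Fixes the imaging geometry and degradation model: illumination enters along
#' +x, detection looks along +z, the sample rotates about +y. Attenuation is
#' Beer-Lambert along straight rays; the point-spread function widens linearly
#' with the summed illumination and detection path inside the sample.
#'
#' @slot lIll,lDet attenuation lengths (um) of nominal tissue for the
#'   illumination and detection paths.
#' @slot sigma0 PSF sigma (um) at zero depth.
#' @slot blurRate dimensionless growth of sigma with depth:
#'   sigma(depth) = sigma0 + blurRate * depth.
#' @slot pitch isotropic voxel pitch (um).
#' @slot stackDim integer length-3, stack shape in voxels (x, y, z).
#' @slot readNoise Gaussian read-noise sigma (counts).
#' @slot photonScale camera gain (counts per photon).
#' @slot noiseSeed integer base seed for shot and read noise.
#' @export
setClass("OpticsConfig", representation(
  lIll = "numeric", lDet = "numeric", sigma0 = "numeric", blurRate = "numeric",
  pitch = "numeric", stackDim = "integer", readNoise = "numeric",
  photonScale = "numeric", noiseSeed = "integer"))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (object@lIll <= 0 || object@lDet <= 0) msg <- c(msg, "attenuation lengths must be > 0")
  if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be > 0")
  if (object@blurRate < 0) msg <- c(msg, "blurRate must be >= 0")
  if (object@pitch <= 0) msg <- c(msg, "voxel pitch must be > 0")
  if (length(object@stackDim) != 3L || any(object@stackDim < 2L))
    msg <- c(msg, "stackDim must be 3 integers >= 2")
  if (object@readNoise < 0 || object@photonScale <= 0)
    msg <- c(msg, "readNoise must be >= 0 and photonScale > 0")
  if (length(msg)) msg else TRUE
})

#' One rotation view: stage angle plus its 3D intensity stack
#'
#' @slot angle rotation-stage angle in degrees, stored modulo 360.
#' @slot stack 3D numeric array (x, y, z) of non-negative intensities.
#' @slot pitch voxel pitch in micrometres.
#' @slot provenance free-text identifier (phantom seed, file of origin, ...).
#' @export
setClass("SpimView", representation(
  angle = "numeric", stack = "array", pitch = "numeric", provenance = "character"))

setValidity("SpimView", function(object) {
  msg <- character()
  if (length(dim(object@stack)) != 3L) msg <- c(msg, "stack must be a 3D array")
  if (any(object@stack < 0)) msg <- c(msg, "stack values must be >= 0")
  if (object@angle < 0 || object@angle >= 360) msg <- c(msg, "angle must be in [0, 360)")
  if (object@pitch <= 0) msg <- c(msg, "pitch must be > 0")
  if (length(msg)) msg else TRUE
})

#' Block-wise spectral-entropy map
#'
#' Shannon entropy (nats) of the normalised DCT-II power spectrum, one value
#' per block on a regular tiling of a 2D image (values is nbx x nby) or of
#' every z-plane of a stack (values is nbx x nby x nz). Blocks with no signal
#' carry NA and are flagged in \code{empty}; a dark block carries no
#' information content and must not masquerade as perfectly structured.
#'
#' @slot values numeric array of entropies, NA where empty.
#' @slot empty logical array, TRUE for all-zero (or below-floor) blocks.
#' @slot blockSize,stride tiling parameters in pixels.
#' @slot sourceDim dimensions of the source image or stack.
#' @export
setClass("EntropyMap", representation(
  values = "array", empty = "array", blockSize = "integer",
  stride = "integer", sourceDim = "integer"))

setValidity("EntropyMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@empty)))
    msg <- c(msg, "values and empty must have identical dimensions")
  ok <- object@values[!object@empty]
  hi <- 2 * log(object@blockSize) + 1e-9
  if (any(ok < -1e-9 | ok > hi, na.rm = TRUE))
    msg <- c(msg, "entropies must lie in [0, 2*log(blockSize)]")
  if (length(msg)) msg else TRUE
})

#' Per-view projections used by the on-the-fly workflow
#'
#' The 3D registration problem is collapsed to 2D: a maximum-intensity
#' projection of the raw stack along the rotation axis (y), and a
#' minimum-entropy projection of the per-plane entropy maps on the matching
#' (x-block, z-plane) grid.
#'
#' @slot angle stage angle in degrees.
#' @slot rawMip numeric matrix (x, z), max intensity over y.
#' @slot entropy numeric matrix (x-blocks, z), min block entropy over y.
#' @slot empty logical matrix, TRUE where every block along y was empty.
#' @slot blockSize,stride block edge and tile step (pixels) of the underlying
#'   entropy map.
#' @slot pitch voxel pitch (um).
#' @export
setClass("ViewProjection", representation(
  angle = "numeric", rawMip = "matrix", entropy = "matrix",
  empty = "matrix", blockSize = "integer", stride = "integer",
  pitch = "numeric"))

#' 2D rigid transform between registered projections
#'
#' Maps moving-frame pixel coordinates p = (x, z) into the reference frame as
#' R(rotation) (p - center) + center + (tx, tz).
#'
#' @slot rotation rotation in degrees, stored modulo 360.
#' @slot tx,tz translation in pixels.
#' @slot center centre of rotation in pixel coordinates (x, z).
#' @slot residual normalised mean absolute difference over the overlap after
#'   warping (0 = perfect).
#' @slot flags character vector; "nominal-only" marks a featureless pair where
#'   the stage transform was used unrefined.
#' @export
setClass("RigidTransform2D", representation(
  rotation = "numeric", tx = "numeric", tz = "numeric", center = "numeric",
  residual = "numeric", flags = "character"))

setValidity("RigidTransform2D", function(object) {
  if (length(object@center) != 2L) "center must be (x, z)" else TRUE
})

#' Fitted von Mises response of one angular region
#'
#' The measured foreground count of an angular region as a function of imaging
#' angle x is modelled as C(x) = A / (2 pi I0(kappa)) * exp(kappa cos(x - mu)).
#' A encodes the region's fluorophore content, kappa its optical accessibility
#' (large kappa = usable from few angles), mu the optimal imaging angle.
#'
#' @slot A amplitude in foreground-block units (integral of the curve).
#' @slot kappa concentration, >= 0.
#' @slot mu optimal imaging angle in degrees, modulo 360.
#' @slot cMax peak value A e^kappa / (2 pi I0(kappa)).
#' @slot fwhm full width at half maximum in degrees (360 when the half level
#'   is never reached).
#' @slot rss residual sum of squares of the fit.
#' @slot flags any of "multi_peak", "degenerate", "capped", "nonconverged".
#' @export
setClass("VonMisesFit", representation(
  A = "numeric", kappa = "numeric", mu = "numeric", cMax = "numeric",
  fwhm = "numeric", rss = "numeric", flags = "character"))

setValidity("VonMisesFit", function(object) {
  msg <- character()
  if (object@A < 0) msg <- c(msg, "A must be >= 0")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (object@fwhm <= 0 || object@fwhm > 360) msg <- c(msg, "fwhm must be in (0, 360]")
  if (length(msg)) msg else TRUE
})

#' Full angular response model of one sample
#'
#' One von Mises fit per angular region (36 regions of 10 degrees by default)
#' plus the raw response profiles they were fitted to and the acquisition
#' metadata needed for update steps.
#'
#' @slot profiles data.frame with columns \code{region_start_deg},
#'   \code{view_angle_deg}, \code{foreground_blocks}.
#' @slot fits list of \linkS4class{VonMisesFit}, one per region, named by the
#'   region start angle.
#' @slot binWidth angular bin width in degrees.
#' @slot background background entropy level (nats) used for foreground calls.
#' @slot viewAngles stage angles (degrees) contributing samples.
#' @slot meta list of provenance details (block size, registration mode, ...).
#' @export
setClass("SampleProfile", representation(
  profiles = "data.frame", fits = "list", binWidth = "numeric",
  background = "numeric", viewAngles = "numeric", meta = "list"))

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (360 %% object@binWidth != 0) msg <- c(msg, "360 must be divisible by binWidth")
  if (length(object@fits) && length(object@fits) != 360 / object@binWidth)
    msg <- c(msg, "need exactly one fit per angular region")
  if (length(msg)) msg else TRUE
})

#' Scored combination of imaging angles
#'
#' @slot angles selected view angles in degrees.
#' @slot perRegion predicted coverage fraction per angular region, in [0, 1]:
#'   additively combined response capped at the region's fitted optimum.
#' @slot meanCoverage arithmetic mean of the per-region fractions.
#' @slot method "exhaustive" or "greedy".
#' @export
setClass("ViewSetScore", representation(
  angles = "numeric", perRegion = "numeric", meanCoverage = "numeric",
  method = "character"))

setValidity("ViewSetScore", function(object) {
  msg <- character()
  if (anyDuplicated(wrapDeg(object@angles))) msg <- c(msg, "angles must be distinct")
  if (any(object@perRegion < -1e-9 | object@perRegion > 1 + 1e-9))
    msg <- c(msg, "coverage fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d emitters in ellipsoidal shell r=(%g, %g, %g) um, thickness %g um\n",
              nrow(object@emitters), object@shellRadii[1], object@shellRadii[2],
              object@shellRadii[3], object@shellThickness))
  if (length(object@densityAmplitude) && any(object@densityAmplitude != 0))
    cat(sprintf("  azimuthal modulation: %s\n",
                paste(sprintf("%.2f*cos(%g*(phi-%g))", object@densityAmplitude,
                              object@densityOrder, object@densityPhaseDeg), collapse = " + ")))
  if (nrow(object@obstructions))
    cat(sprintf("  %d obstruction sector(s)\n", nrow(object@obstructions)))
  cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "OpticsConfig", function(object) {
  cat(sprintf("OpticsConfig: stack %s @ %g um, l_ill=%g um, l_det=%g um, sigma0=%g um, k=%g\n",
              paste(object@stackDim, collapse = "x"), object@pitch, object@lIll,
              object@lDet, object@sigma0, object@blurRate))
})

setMethod("show", "SpimView", function(object) {
  cat(sprintf("SpimView: angle %.1f deg, stack %s, pitch %g um [%s]\n", object@angle,
              paste(dim(object@stack), collapse = "x"), object@pitch, object@provenance))
})

setMethod("show", "EntropyMap", function(object) {
  cat(sprintf("EntropyMap: grid %s, block %d px (stride %d), %d/%d blocks empty\n",
              paste(dim(object@values), collapse = "x"), object@blockSize,
              object@stride, sum(object@empty), length(object@empty)))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: rot %.3f deg, t=(%.3f, %.3f) px, centre (%.1f, %.1f), residual %.4f%s\n",
              object@rotation, object@tx, object@tz, object@center[1], object@center[2],
              object@residual, if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "VonMisesFit", function(object) {
  cat(sprintf("VonMisesFit: A=%.1f, kappa=%.3f, mu=%.1f deg, Cmax=%.1f, FWHM=%.1f deg%s\n",
              object@A, object@kappa, object@mu, object@cMax, object@fwhm,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile: %d regions x %d deg, %d views, background %.3f nats\n",
              length(object@fits), object@binWidth, length(object@viewAngles),
              object@background))
  if (length(object@fits)) {
    mus <- vapply(object@fits, function(f) f@mu, numeric(1))
    kap <- vapply(object@fits, function(f) f@kappa, numeric(1))
    cat(sprintf("  kappa: median %.2f [%.2f, %.2f]; mu span of fits: %d regions\n",
                stats::median(kap), min(kap), max(kap), length(mus)))
  }
})

setMethod("show", "ViewSetScore", function(object) {
  cat(sprintf("ViewSetScore (%s): angles {%s} deg, mean coverage %.3f\n", object@method,
              paste(format(object@angles), collapse = ", "), object@meanCoverage))
})

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("viewAngle", function(x) standardGeneric("viewAngle"))
#' @rdname accessors
#' @export
setGeneric("stackArray", function(x) standardGeneric("stackArray"))
#' @rdname accessors
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))
#' @rdname accessors
#' @export
setGeneric("emptyMask", function(x) standardGeneric("emptyMask"))
#' @rdname accessors
#' @export
setGeneric("blockSize", function(x) standardGeneric("blockSize"))
#' @rdname accessors
#' @export
setGeneric("emitterPositions", function(x) standardGeneric("emitterPositions"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))
#' @rdname accessors
#' @export
setGeneric("peakAngle", function(x) standardGeneric("peakAngle"))
#' @rdname accessors
#' @export
setGeneric("peakValue", function(x) standardGeneric("peakValue"))
#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setGeneric("regionFits", function(x) standardGeneric("regionFits"))
#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname accessors
#' @export
setGeneric("selectedAngles", function(x) standardGeneric("selectedAngles"))
#' @rdname accessors
#' @export
setGeneric("meanCoverage", function(x) standardGeneric("meanCoverage"))

#' Accessors for smartRotate classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x an object of the documented classes.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("viewAngle", "SpimView", function(x) x@angle)
#' @rdname accessors
setMethod("viewAngle", "ViewProjection", function(x) x@angle)
#' @rdname accessors
setMethod("stackArray", "SpimView", function(x) x@stack)
#' @rdname accessors
setMethod("entropyValues", "EntropyMap", function(x) x@values)
#' @rdname accessors
setMethod("entropyValues", "ViewProjection", function(x) x@entropy)
#' @rdname accessors
setMethod("emptyMask", "EntropyMap", function(x) x@empty)
#' @rdname accessors
setMethod("emptyMask", "ViewProjection", function(x) x@empty)
#' @rdname accessors
setMethod("blockSize", "EntropyMap", function(x) x@blockSize)
#' @rdname accessors
setMethod("blockSize", "ViewProjection", function(x) x@blockSize)
#' @rdname accessors
setMethod("emitterPositions", "Phantom", function(x) x@emitters)
#' @rdname accessors
setMethod("amplitude", "VonMisesFit", function(x) x@A)
#' @rdname accessors
setMethod("concentration", "VonMisesFit", function(x) x@kappa)
#' @rdname accessors
setMethod("peakAngle", "VonMisesFit", function(x) x@mu)
#' @rdname accessors
setMethod("peakValue", "VonMisesFit", function(x) x@cMax)
#' @rdname accessors
setMethod("fitFlags", "VonMisesFit", function(x) x@flags)
#' @rdname accessors
setMethod("regionFits", "SampleProfile", function(x) x@fits)
#' @rdname accessors
setMethod("profileTable", "SampleProfile", function(x) x@profiles)
#' @rdname accessors
setMethod("selectedAngles", "ViewSetScore", function(x) x@angles)
#' @rdname accessors
setMethod("meanCoverage", "ViewSetScore", function(x) x@meanCoverage)
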
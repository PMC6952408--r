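# Shared simulation fixtures, generated in code and memoised per test run.
# Unit tests use a reduced geometry (64^3 voxels at 6 um pitch: same 384 um
# field of view and physics as the default 128^3 / 3 um, at 1/8 the voxel
# count); the acceptance suite builds the full default geometry itself.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

smallOptics <- function(noiseSeed = 5L)
  spimOptics(pitch = 6, stackDim = c(64L, 64L, 64L), noiseSeed = noiseSeed)

smallPhantom <- function(seed = 5L, ...)
  makePhantom(baseDensity = 6e-4, seed = seed, ...)

# one small noisy view plus its projection, shared across tests
smallView <- function() memo("smallView", {
  v <- acquireView(smallPhantom(), smallOptics(), 0)
  list(view = v, proj = projectView(v, entropyMap(v, blockSize = 8L, stride = 4L)))
})

smallBackground <- function() memo("smallBackground",
  calibrateBackground(acquireBlank(smallOptics()), blockSize = 8L,
                      stride = 4L, margin = 0.5))

# full reduced-geometry multi-view pipeline (24 views)
smallPipeline <- function() memo("smallPipeline", {
  ph <- smallPhantom()
  op <- smallOptics()
  angles <- seq(0, 345, by = 15)
  mv <- acquireMultiView(ph, op, angles)
  prs <- lapply(mv$views, function(v)
    projectView(v, entropyMap(v, blockSize = 8L, stride = 4L)))
  tfs <- suppressMessages(registerViews(prs))
  bg <- smallBackground()
  prof <- buildProfiles(prs, tfs, bg)
  list(phantom = ph, optics = op, angles = angles, mv = mv,
       projections = prs, transforms = tfs, background = bg,
       profiles = prof,
       profile = fitSampleProfile(prof, background = bg))
})

# synthetic 36-region sample profile from explicit von Mises parameters
syntheticProfile <- function(A, kappa, mu, binWidth = 10,
                             viewAngles = seq(0, 345, by = 15)) {
  starts <- seq(0, 360 - binWidth, by = binWidth)
  n <- length(starts)
  A <- rep_len(A, n); kappa <- rep_len(kappa, n); mu <- rep_len(mu, n)
  fits <- lapply(seq_len(n), function(i)
    new("VonMisesFit", A = A[i], kappa = kappa[i], mu = wrapDeg(mu[i]),
        cMax = vonMisesCurve(mu[i], A[i], kappa[i], mu[i]),
        fwhm = fwhmAccessibility(kappa[i]), rss = 0, flags = character()))
  names(fits) <- starts
  new("SampleProfile", profiles = data.frame(
        region_start_deg = numeric(), view_angle_deg = numeric(),
        foreground_blocks = integer()),
      fits = fits, binWidth = binWidth, background = NA_real_,
      viewAngles = viewAngles, meta = list())
}

circMeanDeg <- function(a) {
  r <- a * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}
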
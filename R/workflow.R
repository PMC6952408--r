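# Offline orchestration of the smart-rotation workflow over directories of
# view stacks: simulate -> evaluate -> update, with machine-readable reports.
# The acquisition/analysis split is honoured at the file level: every stage
# is a pure function over files, so an acquisition loop can poll reports.

# ---- configuration ---------------------------------------------------------

#' Default simulation configuration
#'
#' A moderately inhomogeneous embryo: one dominant azimuthal density lobe
#' (amplitude 0.8 at 90 degrees) and one strongly absorbing obstruction
#' sector over [180, 260) degrees (0.08 per um extra attenuation, pigment
#' patch-like), imaged from 24 equally spaced angles.
#'
#' @param seed integer seed driving phantom sampling and noise.
#' @param nAngles number of equally spaced evaluation angles (default 24).
#' @param stackDim stack shape in voxels.
#' @param pitch voxel pitch (um).
#' @return nested configuration list (phantom / optics / acquisition).
#' @export
defaultSimConfig <- function(seed = 7L, nAngles = 24L,
                             stackDim = c(128L, 128L, 128L), pitch = 3) {
  list(
    phantom = list(
      shell_radii = c(130, 160, 130), shell_thickness = 30,
      base_density = 1e-3,
      mod_amplitude = c(0.8), mod_phase_deg = c(90), mod_order = c(1),
      obstructions = list(list(phi1 = 180, phi2 = 260, r1 = 0, r2 = 200,
                               extra = 0.08)),
      attenuation_base = 0, intensity = 3000, seed = as.integer(seed)),
    optics = list(
      l_ill = 30, l_det = 30, sigma0 = 4, blur_rate = 0.02,
      pitch = pitch, stack_dim = as.integer(stackDim), read_noise = 2,
      photon_scale = 1, noise_seed = as.integer(seed)),
    acquisition = list(n_angles = as.integer(nAngles)))
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file with phantom / optics / acquisition sections; seeds
#'   are mandatory.
#' @return configuration list.
#' @export
readSimConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phantom$seed) || is.null(cfg$optics$noise_seed))
    stop("config must specify phantom$seed and optics$noise_seed")
  cfg
}

configPhantom <- function(cfg) {
  p <- cfg$phantom
  obs <- if (length(p$obstructions)) {
    do.call(rbind, lapply(p$obstructions, function(o)
      data.frame(phi1 = o$phi1, phi2 = o$phi2, r1 = o$r1, r2 = o$r2,
                 extra = o$extra)))
  } else emptyObstructions()
  makePhantom(shellRadii = unlist(p$shell_radii),
              shellThickness = p$shell_thickness,
              baseDensity = p$base_density,
              modAmplitude = unlist(p$mod_amplitude) %||% numeric(),
              modPhaseDeg = unlist(p$mod_phase_deg) %||% numeric(),
              modOrder = unlist(p$mod_order) %||% rep(1, length(unlist(p$mod_amplitude))),
              obstructions = obs,
              attenuationBase = p$attenuation_base %||% 0,
              intensity = p$intensity %||% 3000, seed = p$seed)
}

configOptics <- function(cfg) {
  o <- cfg$optics
  spimOptics(lIll = o$l_ill, lDet = o$l_det, sigma0 = o$sigma0,
             blurRate = o$blur_rate, pitch = o$pitch,
             stackDim = unlist(o$stack_dim), readNoise = o$read_noise,
             photonScale = o$photon_scale, noiseSeed = o$noise_seed)
}

# ---- bundle I/O ------------------------------------------------------------

writeStackTiff <- function(stack, path, scale) {
  planes <- lapply(seq_len(dim(stack)[3]), function(k)
    pmin(pmax(stack[, , k] / scale, 0), 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "none")
}

readStackTiff <- function(path, scale) {
  planes <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) stack[, , k] <- planes[[k]]
  stack * scale
}

#' Simulate a multi-view bundle to disk
#'
#' Writes one multi-page 32-bit float TIFF per view
#' (\code{view_<angle>.tif}), a blank noise view for background calibration,
#' a \code{views.json} manifest (angle, file, seed, intensity scale) and the
#' noiseless ground-truth coverage table \code{ground_truth.csv}. Re-running
#' with the same configuration reproduces the bundle bit-exactly.
#'
#' @param config configuration list (see \code{\link{defaultSimConfig}}) or a
#'   YAML path.
#' @param outDir output directory, created if needed.
#' @return path to the manifest, invisibly.
#' @export
simulateViews <- function(config = defaultSimConfig(), outDir) {
  if (is.character(config)) config <- readSimConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phantom <- configPhantom(config)
  optics <- configOptics(config)
  n <- config$acquisition$n_angles
  angles <- seq(0, 360 - 360 / n, by = 360 / n)
  mv <- acquireMultiView(phantom, optics, angles, noise = TRUE)
  blank <- acquireBlank(optics)
  scale <- max(vapply(mv$views, function(v) max(stackArray(v)), numeric(1)),
               max(stackArray(blank))) * 1.05
  entries <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    fn <- sprintf("view_%03d.tif", as.integer(round(angles[i])))
    writeStackTiff(stackArray(mv$views[[i]]), file.path(outDir, fn), scale)
    entries[[i]] <- list(angle = angles[i], file = fn,
                         seed = viewSeed(optics@noiseSeed, angles[i]))
  }
  writeStackTiff(stackArray(blank), file.path(outDir, "blank.tif"), scale)
  utils::write.csv(mv$groundTruth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(pitch = optics@pitch, scale = scale, views = entries,
                   blank = "blank.tif", ground_truth = "ground_truth.csv",
                   config = config)
  jsonlite::write_json(manifest, file.path(outDir, "views.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(outDir, "views.json"))
}

#' Read a view bundle from a manifest
#'
#' @param manifestPath path to \code{views.json}.
#' @param files optional subset of view file names to load.
#' @return list with \code{views} (list of \linkS4class{SpimView}),
#'   \code{blank} and \code{manifest}.
#' @export
readViewBundle <- function(manifestPath, files = NULL) {
  man <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  entries <- man$views
  if (!is.null(files))
    entries <- Filter(function(e) e$file %in% files, entries)
  if (length(entries) == 0L) stop("no views selected from the manifest")
  views <- lapply(entries, function(e) {
    fp <- file.path(dir, e$file)
    if (!file.exists(fp)) stop("missing view file: ", fp)
    new("SpimView", angle = wrapDeg(e$angle),
        stack = readStackTiff(fp, man$scale), pitch = man$pitch,
        provenance = e$file)
  })
  blank <- NULL
  if (!is.null(man$blank) && file.exists(file.path(dir, man$blank)))
    blank <- new("SpimView", angle = 0,
                 stack = readStackTiff(file.path(dir, man$blank), man$scale),
                 pitch = man$pitch, provenance = man$blank)
  list(views = views, blank = blank, manifest = man)
}

#' Down-sample a stack by integer striding
#'
#' @param stack 3D array.
#' @param factors integer length-3 striding factors (x, y, z).
#' @return the strided stack.
#' @export
downsampleStack <- function(stack, factors = c(1L, 1L, 1L)) {
  d <- dim(stack)
  stack[seq(1, d[1], by = factors[1]), seq(1, d[2], by = factors[2]),
        seq(1, d[3], by = factors[3]), drop = FALSE]
}

# ---- profile / selection serialization -------------------------------------

#' Serialize and restore sample profiles
#'
#' JSON round-trip of a \linkS4class{SampleProfile}: per-region fit
#' parameters plus the raw response table. The reference projection kept in
#' memory for update steps is not serialized.
#'
#' @param sp a \linkS4class{SampleProfile}.
#' @param path JSON file path.
#' @return \code{readSampleProfile} returns the restored object.
#' @export
writeSampleProfile <- function(sp, path) {
  fits <- regionFits(sp)
  regions <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    list(start_deg = as.numeric(nm), A = f@A, kappa = f@kappa, mu_deg = f@mu,
         c_max = f@cMax, fwhm_deg = f@fwhm, rss = f@rss,
         flags = as.list(f@flags))
  })
  obj <- list(bin_width_deg = sp@binWidth, background_nats = sp@background,
              view_angles_deg = sp@viewAngles, regions = regions,
              profiles = sp@profiles,
              meta = sp@meta[setdiff(names(sp@meta), "refMip")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname writeSampleProfile
#' @export
readSampleProfile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  fits <- list()
  for (i in seq_len(nrow(obj$regions))) {
    r <- obj$regions[i, ]
    fl <- r$flags[[1]]
    fits[[as.character(r$start_deg)]] <- new(
      "VonMisesFit", A = r$A, kappa = r$kappa, mu = r$mu_deg, cMax = r$c_max,
      fwhm = r$fwhm_deg, rss = r$rss,
      flags = if (length(fl)) as.character(unlist(fl)) else character())
  }
  prof <- as.data.frame(obj$profiles)
  new("SampleProfile", profiles = prof, fits = fits,
      binWidth = obj$bin_width_deg, background = obj$background_nats,
      viewAngles = as.numeric(obj$view_angles_deg),
      meta = as.list(obj$meta))
}

writeSelection <- function(sel, path, extra = list()) {
  obj <- c(list(n = length(selectedAngles(sel)), method = sel@method,
                angles_deg = selectedAngles(sel),
                mean_coverage = meanCoverage(sel),
                per_region_fraction = as.list(sel@perRegion)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- pipeline stages -------------------------------------------------------

# quality + projection for a list of views
processViews <- function(views, blockSize = 16L, stride = blockSize,
                         downsample = c(1L, 1L, 1L)) {
  lapply(views, function(v) {
    st <- stackArray(v)
    if (any(downsample > 1L)) {
      st <- downsampleStack(st, downsample)
      v <- new("SpimView", angle = viewAngle(v), stack = st,
               pitch = v@pitch * downsample[1], provenance = v@provenance)
    }
    projectView(v, entropyMap(st, blockSize = blockSize, stride = stride))
  })
}

#' Run the full evaluation step
#'
#' The evaluation step of the smart-rotation workflow: quality maps,
#' projection registration, background calibration, angular response
#' profiles, von Mises fits and view selection, over a bundle of N equally
#' spaced views (24 recommended; fewer degrades registration and the
#' coverage estimate). Reports (profile JSON, selection JSON, per-view
#' response CSV, log) are written when \code{outDir} is given; the run is
#' deterministic for identical inputs.
#'
#' @param manifestPath path to a \code{views.json} manifest.
#' @param blockSize entropy block size in pixels (default 8, sized so the
#'   block grid keeps roughly 16 tiles across the field of view).
#' @param stride tile step in pixels; the default blockSize/2 samples the
#'   response on an overlapping grid, which stabilises the angular profiles
#'   without changing the metric.
#' @param binWidth angular bin width in degrees (default 10).
#' @param background "auto" (calibrate from the bundle's blank view) or a
#'   numeric level in nats.
#' @param backgroundMargin nats subtracted below the blank level (default
#'   0.5): guards against sub-noise signal smears counting as foreground.
#' @param nViews number of views to select (default 4).
#' @param method selection method, "exhaustive" or "greedy".
#' @param engine registration engine (see
#'   \code{\link{registerProjectionPair}}).
#' @param downsample integer striding factors (x, y, z) applied before
#'   analysis; trades accuracy for speed.
#' @param outDir optional report directory.
#' @return list with \code{profile} (\linkS4class{SampleProfile}),
#'   \code{selection} (\linkS4class{ViewSetScore}) and \code{projections}.
#' @export
evaluateViews <- function(manifestPath, blockSize = 8L, stride = blockSize %/% 2L,
                          binWidth = 10, background = "auto",
                          backgroundMargin = 0.5, nViews = 4L,
                          method = "exhaustive", engine = "phasecorr",
                          downsample = c(1L, 1L, 1L), outDir = NULL) {
  bundle <- readViewBundle(manifestPath)
  views <- bundle$views
  if (length(views) < 4L) stop("evaluation needs at least 4 views with angles")
  if (length(views) < 24L)
    warning(sprintf("only %d views: fewer than 24 angles gives less accurate registration and coverage estimates",
                    length(views)))
  angs <- sort(wrapDeg(vapply(views, viewAngle, numeric(1))))
  gaps <- diff(c(angs, angs[1] + 360))
  if (max(gaps) > 180)
    stop(sprintf("angular gap of %.0f deg (> 180) between views %.0f and %.0f deg",
                 max(gaps), angs[which.max(gaps)],
                 angs[(which.max(gaps) %% length(angs)) + 1]))
  t0 <- Sys.time()
  projections <- processViews(views, blockSize = blockSize, stride = stride,
                              downsample = downsample)
  tQuality <- Sys.time()
  transforms <- registerViews(projections, engine = engine)
  tRegister <- Sys.time()
  bg <- if (identical(background, "auto")) {
    if (is.null(bundle$blank))
      stop("background = \"auto\" needs a blank view in the bundle")
    blankStack <- stackArray(bundle$blank)
    if (any(downsample > 1L)) blankStack <- downsampleStack(blankStack, downsample)
    calibrateBackground(blankStack, blockSize = blockSize, stride = stride,
                        margin = backgroundMargin)
  } else as.numeric(background)
  profiles <- buildProfiles(projections, transforms, bg, binWidth = binWidth)
  refIdx <- which.min(circDistDeg(vapply(projections, viewAngle, numeric(1)), 0))
  meta <- list(blockSize = blockSize, stride = stride, engine = engine,
               downsample = as.integer(downsample),
               background_mode = if (identical(background, "auto")) "auto" else "value",
               manifest = manifestPath,
               refMip = projections[[refIdx]]@rawMip,
               center = transforms[[1]]@center)
  sp <- fitSampleProfile(profiles, binWidth = binWidth, background = bg,
                         meta = meta)
  sel <- selectViews(sp, nViews, method = method)
  tFit <- Sys.time()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSampleProfile(sp, file.path(outDir, "profile.json"))
    cfg <- list(block_size = blockSize, bin_width_deg = binWidth,
                background_nats = bg, n_views = nViews, method = method,
                engine = engine, downsample = as.integer(downsample),
                manifest = manifestPath)
    writeSelection(sel, file.path(outDir, "selection.json"),
                   extra = list(config = cfg))
    utils::write.csv(profiles, file.path(outDir, "profiles.csv"),
                     row.names = FALSE)
    log <- c(sprintf("quality: %.2f s", as.numeric(tQuality - t0, units = "secs")),
             sprintf("registration: %.2f s", as.numeric(tRegister - tQuality, units = "secs")),
             sprintf("fit+selection: %.2f s", as.numeric(tFit - tRegister, units = "secs")))
    writeLines(log, file.path(outDir, "evaluate.log"))
  }
  list(profile = sp, selection = sel, projections = projections,
       transforms = transforms, background = bg)
}

#' Run an update step
#'
#' Processes only the newly acquired views through quality and registration,
#' substitutes their samples into the stored profile, refits every region and
#' reselects the views. When \code{outDir} is given, the selected angles are
#' appended to \code{selection_trace.csv} (one row per update), giving the
#' time series of selected angles over a time-lapse.
#'
#' @param manifestPath manifest listing the new view files (angles must exist
#'   in the stored profile's grid).
#' @param previous a \linkS4class{SampleProfile} or the path to a profile
#'   JSON.
#' @param newFiles character vector of view file names to process.
#' @inheritParams evaluateViews
#' @return list with \code{profile}, \code{selection} and
#'   \code{viewsProcessed} (work accounting: exactly the new views).
#' @export
updateEvaluation <- function(manifestPath, previous, newFiles,
                             blockSize = NULL, nViews = 4L,
                             method = "exhaustive", engine = "phasecorr",
                             downsample = c(1L, 1L, 1L), outDir = NULL) {
  sp <- if (is.character(previous)) readSampleProfile(previous) else previous
  if (length(newFiles) == 0L) {
    sel <- selectViews(sp, nViews, method = method)
    return(list(profile = sp, selection = sel, viewsProcessed = 0L))
  }
  blockSize <- as.integer(blockSize %||% sp@meta$blockSize %||% 8L)
  stride <- as.integer(sp@meta$stride %||% blockSize)
  bundle <- readViewBundle(manifestPath, files = newFiles)
  projections <- processViews(bundle$views, blockSize = blockSize,
                              stride = stride, downsample = downsample)
  refMip <- sp@meta$refMip
  center <- as.numeric(sp@meta$center %||% ((dim(projections[[1]]@rawMip) + 1) / 2))
  transforms <- list()
  for (proj in projections) {
    a <- viewAngle(proj)
    tf <- if (!is.null(refMip))
      registerProjectionPair(refMip, proj@rawMip, a, engine = engine,
                             center = center)
    else rigidTransform2D(a, 0, 0, center, flags = "nominal-only")
    transforms[[as.character(a)]] <- tf
  }
  newProfiles <- buildProfiles(projections, transforms, sp@background,
                               binWidth = sp@binWidth)
  sp2 <- updateSampleProfile(sp, newProfiles)
  sp2@meta <- sp@meta
  sel <- selectViews(sp2, nViews, method = method)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSampleProfile(sp2, file.path(outDir, "profile.json"))
    writeSelection(sel, file.path(outDir, "selection.json"))
    tracePath <- file.path(outDir, "selection_trace.csv")
    row <- data.frame(step = NA_integer_,
                      angles = paste(selectedAngles(sel), collapse = ";"),
                      mean_coverage = meanCoverage(sel))
    if (file.exists(tracePath)) {
      prev <- utils::read.csv(tracePath, stringsAsFactors = FALSE)
      row$step <- max(prev$step) + 1L
      utils::write.csv(rbind(prev, row), tracePath, row.names = FALSE)
    } else {
      row$step <- 1L
      utils::write.csv(row, tracePath, row.names = FALSE)
    }
  }
  list(profile = sp2, selection = sel,
       viewsProcessed = length(projections))
}

#' Mean coverage versus number of views, smart and blind
#'
#' Sweeps n from 1 to \code{maxViews}: the smart column is the greedy
#' selection's mean coverage (its increments are the marginal gains of each
#' added view); the blind columns score equally spaced sets snapped to the
#' candidate grid, reporting their best, mean and worst over all offsets.
#'
#' @param sampleProfile a \linkS4class{SampleProfile}.
#' @param maxViews largest set size (default 8).
#' @param candidates candidate angles; defaults to the measured grid.
#' @param outCsv optional CSV path.
#' @return data.frame with columns \code{n}, \code{smart}, \code{blind_best},
#'   \code{blind_mean}, \code{blind_worst}.
#' @export
coverageCurve <- function(sampleProfile, maxViews = 8L, candidates = NULL,
                          outCsv = NULL) {
  if (is.null(candidates)) candidates <- sampleProfile@viewAngles
  candidates <- sort(wrapDeg(candidates))
  rows <- lapply(seq_len(maxViews), function(n) {
    smart <- selectViews(sampleProfile, n, candidates, method = "greedy")
    blind <- blindSetScores(sampleProfile, n, candidates)
    data.frame(n = n, smart = meanCoverage(smart),
               blind_best = max(blind), blind_mean = mean(blind),
               blind_worst = min(blind))
  })
  out <- do.call(rbind, rows)
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  out
}

# scores of every equally spaced n-set realisable on the candidate grid
blindSetScores <- function(sampleProfile, n, candidates) {
  candidates <- sort(wrapDeg(candidates))
  step <- 360 / n
  offsets <- candidates[candidates < step]
  if (length(offsets) == 0L) offsets <- candidates[1]
  vapply(offsets, function(a) {
    ideal <- wrapDeg(a + step * (seq_len(n) - 1))
    snapped <- unique(vapply(ideal, function(x)
      candidates[which.min(circDistDeg(candidates, x))], numeric(1)))
    if (length(snapped) < n) return(NA_real_)
    meanCoverage(scoreViewSet(sampleProfile, snapped, method = "blind"))
  }, numeric(1)) |> stats::na.omit() |> as.numeric()
}
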
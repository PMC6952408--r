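# Circular coverage model: the response of an angular region to the imaging
# angle is modelled as a scaled von Mises curve. Amplitude A carries the
# region's fluorophore content (the integral of the curve over one turn),
# concentration kappa its optical accessibility, location mu the optimal
# imaging angle.

#' Evaluate the von Mises coverage curve
#'
#' C(x) = A / (2 pi I0(kappa)) * exp(kappa cos(x - mu)), periodic in x with
#' period 360 degrees. Evaluated with exponentially scaled Bessel terms so
#' large kappa stays finite. The integral of C over one full turn (x in
#' radians) equals A for any kappa; at kappa = 0 the curve is the uniform
#' level A / (2 pi).
#'
#' @param x imaging angle(s) in degrees.
#' @param A amplitude (foreground-block units), >= 0.
#' @param kappa concentration, >= 0.
#' @param mu location (optimal imaging angle) in degrees.
#' @return C evaluated at x.
#' @examples
#' vonMisesCurve(c(0, 90, 130), A = 5000, kappa = 2, mu = 130)
#' @export
vonMisesCurve <- function(x, A, kappa, mu) {
  if (kappa < 0) stop("kappa must be >= 0")
  # exp(kappa cos d) / I0(kappa) = exp(kappa (cos d - 1)) / (I0(kappa) e^-kappa)
  d <- degToRad(x - mu)
  A * exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname vonMisesCurve
#' @param fit a \linkS4class{VonMisesFit} whose curve to evaluate.
#' @export
predictResponse <- function(fit, x) vonMisesCurve(x, fit@A, fit@kappa, fit@mu)

# peak of the curve, at x = mu
vmPeak <- function(A, kappa)
  A / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))

#' Full width at half maximum of a fitted von Mises curve
#'
#' The optical accessibility of a region: a wide curve means the region is
#' imaged well from many angles. Closed form: the half level is reached where
#' cos(x - mu) = 1 - ln(2)/kappa, so FWHM = 2 arccos(1 - ln(2)/kappa); when
#' ln(2)/kappa > 2 (kappa < ln(2)/2) the half level is never reached and the
#' width is 360 degrees by convention, as it is for kappa = 0.
#'
#' @param fit a \linkS4class{VonMisesFit}, or a numeric kappa.
#' @return width in degrees, in (0, 360].
#' @examples
#' fwhmAccessibility(log(2))   # exactly 180 degrees
#' @export
fwhmAccessibility <- function(fit) {
  kappa <- if (is(fit, "VonMisesFit")) fit@kappa else fit
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0 || log(2) / kappa >= 2) return(360)
  radToDeg(2 * acos(1 - log(2) / kappa))
}

# A(kappa) inversion: kappa from the mean resultant length (standard
# piecewise approximation used throughout circular statistics).
kappaFromRbar <- function(r) {
  if (r < 1e-9) return(0)
  if (r >= 1 - 1e-9) return(500)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

# circularly smooth counts ordered by angle (window = 3 samples)
circSmooth3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  (y + y[c(n, 1:(n - 1))] + y[c(2:n, 1)]) / 3
}

# local maxima on the circle, above `frac` of the global max
circPeaks <- function(y, frac = 0.3) {
  n <- length(y)
  prev <- y[c(n, 1:(n - 1))]; nxt <- y[c(2:n, 1)]
  which(y >= prev & y > nxt & y >= frac * max(y))
}

#' Fit the von Mises coverage model to one response profile
#'
#' Nonlinear least squares on (A, kappa, mu) with mu treated circularly.
#' Initialisation is deterministic: mu from the count-weighted circular mean,
#' kappa from the mean resultant length via the standard A(kappa) inversion,
#' A from the trapezoidal mass of the samples. Profiles with several local
#' maxima (after 3-sample circular smoothing) are flagged "multi_peak" and
#' only the highest peak is fitted: samples farther than 90 degrees from it
#' are dropped. If the optimiser fails, 8 seeded restarts are attempted and
#' the best is returned flagged "nonconverged" if none converge. The reported
#' peak value is capped at 1.5 times the largest observed sample (flag
#' "capped"). An all-zero profile yields the degenerate fit A = 0, kappa = 0,
#' flagged "degenerate".
#'
#' @param angles view angles in degrees (>= 4 samples spanning >= 180
#'   degrees).
#' @param counts foreground counts at those angles.
#' @param objective "ols" (default) or "poisson" (deviance weights).
#' @return a \linkS4class{VonMisesFit}.
#' @export
fitVonMises <- function(angles, counts, objective = c("ols", "poisson")) {
  objective <- match.arg(objective)
  stopifnot(length(angles) == length(counts))
  if (length(angles) < 4L) stop("need at least 4 samples")
  angles <- wrapDeg(angles)
  gaps <- diff(c(sort(angles), min(angles) + 360))   # circular gaps
  if (360 - max(gaps) < 180)
    stop("samples must span at least 180 degrees of view angles")
  if (all(counts <= 0)) {
    return(new("VonMisesFit", A = 0, kappa = 0, mu = 0, cMax = 0, fwhm = 360,
               rss = 0, flags = "degenerate"))
  }
  ord <- order(angles)
  aS <- angles[ord]; cS <- counts[ord]
  sm <- circSmooth3(cS)
  pk <- circPeaks(sm)
  flags <- character()
  fitA <- aS; fitC <- cS
  if (length(pk) > 1L) {
    flags <- "multi_peak"
    muPk <- aS[pk[which.max(sm[pk])]]
    keep <- circDistDeg(aS, muPk) <= 90
    fitA <- aS[keep]; fitC <- cS[keep]
  }
  th <- degToRad(fitA)
  w <- pmax(fitC, 0)
  Cs <- sum(w * cos(th)); Ss <- sum(w * sin(th))
  mu0 <- wrapDeg(radToDeg(atan2(Ss, Cs)))
  rbar <- sqrt(Cs^2 + Ss^2) / max(sum(w), 1e-12)
  kappa0 <- min(max(kappaFromRbar(rbar), 1e-3), 100)
  spacing <- 2 * pi / length(angles)              # mean angular spacing, radians
  A0 <- max(sum(pmax(counts, 0)) * spacing, 1e-6)
  doFit <- function(start) {
    df <- data.frame(a = fitA, cc = fitC)
    wts <- if (objective == "poisson") 1 / pmax(fitC, 1) else rep(1, length(fitC))
    tryCatch(
      minpack.lm::nlsLM(
        cc ~ A * exp(kappa * (cos((a - mu) * pi / 180) - 1)) /
          (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)),
        data = df, start = start, weights = wts,
        lower = c(A = 0, kappa = 0, mu = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- doFit(list(A = A0, kappa = kappa0, mu = mu0))
  if (is.null(fit)) {
    best <- NULL; bestRss <- Inf
    jit <- withSeed(20231L, list(k = stats::runif(8, 0.1, 8),
                                 m = stats::runif(8, 0, 360)))
    for (i in 1:8) {
      f <- doFit(list(A = A0, kappa = jit$k[i], mu = jit$m[i]))
      if (!is.null(f)) {
        r <- sum(stats::residuals(f)^2)
        if (r < bestRss) { best <- f; bestRss <- r }
      }
    }
    fit <- best
    if (is.null(fit)) {
      # last resort: report the moment initialisation, flagged
      pars <- c(A = A0, kappa = kappa0, mu = mu0)
      flags <- union(flags, "nonconverged")
      return(vmFitObject(pars, fitA, fitC, counts, flags))
    }
    flags <- union(flags, "nonconverged")
  }
  pars <- stats::coef(fit)
  vmFitObject(pars, fitA, fitC, counts, flags)
}

vmFitObject <- function(pars, fitA, fitC, allCounts, flags) {
  A <- max(pars[["A"]], 0); kappa <- max(pars[["kappa"]], 0)
  mu <- wrapDeg(pars[["mu"]])
  cMax <- vmPeak(A, kappa)
  cap <- 1.5 * max(allCounts)
  if (cMax > cap && cap > 0) {
    A <- A * cap / cMax
    cMax <- cap
    flags <- union(flags, "capped")
  }
  rss <- sum((fitC - vonMisesCurve(fitA, A, kappa, mu))^2)
  new("VonMisesFit", A = as.numeric(A), kappa = as.numeric(kappa),
      mu = as.numeric(mu), cMax = as.numeric(cMax),
      fwhm = fwhmAccessibility(kappa), rss = rss, flags = flags)
}

#' Fit the full sample profile (one von Mises fit per angular region)
#'
#' @param profiles data.frame from \code{\link{buildProfiles}}.
#' @param binWidth angular bin width in degrees (default 10).
#' @param background background level recorded for provenance.
#' @param objective passed to \code{\link{fitVonMises}}.
#' @param meta optional provenance list.
#' @return a \linkS4class{SampleProfile}.
#' @export
fitSampleProfile <- function(profiles, binWidth = 10, background = NA_real_,
                             objective = "ols", meta = list()) {
  starts <- seq(0, 360 - binWidth, by = binWidth)
  fits <- vector("list", length(starts))
  names(fits) <- starts
  for (i in seq_along(starts)) {
    sub <- profiles[profiles$region_start_deg == starts[i], ]
    fits[[i]] <- fitVonMises(sub$view_angle_deg, sub$foreground_blocks,
                             objective = objective)
  }
  new("SampleProfile", profiles = profiles, fits = fits, binWidth = binWidth,
      background = background,
      viewAngles = sort(unique(wrapDeg(profiles$view_angle_deg))), meta = meta)
}
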
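# Scoring and selection of view combinations against the fitted sample
# profile. Combined coverage is additive, capped at each region's fitted
# optimum; the score of a set is the mean over regions of combined coverage
# relative to that optimum.

# matrix of predicted responses: regions x candidate angles
responseMatrix <- function(sampleProfile, candidates) {
  fits <- regionFits(sampleProfile)
  M <- vapply(fits, function(f) predictResponse(f, candidates),
              numeric(length(candidates)))
  matrix(t(M), nrow = length(fits), ncol = length(candidates),
         dimnames = list(names(fits), NULL))
}

regionPeaks <- function(sampleProfile)
  vapply(regionFits(sampleProfile), peakValue, numeric(1))

# coverage fractions for a set of columns of the response matrix
coverageFractions <- function(M, cmax, cols) {
  combined <- if (length(cols)) rowSums(M[, cols, drop = FALSE]) else
    rep(0, nrow(M))
  combined <- pmin(combined, cmax)
  ifelse(cmax > 0, combined / cmax, 1)
}

# deterministic tie-break key: larger minimal pairwise circular spacing wins,
# then lexicographically smaller sorted angle set
minSpacing <- function(angles) {
  if (length(angles) < 2) return(360)
  s <- sort(wrapDeg(angles))
  min(diff(c(s, s[1] + 360)))
}

#' Score a combination of imaging angles
#'
#' For each angular region the combined coverage of the chosen angles is the
#' sum of the fitted von Mises responses, capped at the region's fitted
#' optimum C_max; the region fraction is combined / C_max (1 where C_max is
#' 0), and the set score is the arithmetic mean over regions.
#'
#' @param sampleProfile a \linkS4class{SampleProfile}.
#' @param angles view angles in degrees (distinct).
#' @param method label recorded in the result.
#' @return a \linkS4class{ViewSetScore}.
#' @export
scoreViewSet <- function(sampleProfile, angles, method = "manual") {
  angles <- wrapDeg(angles)
  if (anyDuplicated(angles)) stop("angles must be distinct")
  M <- responseMatrix(sampleProfile, angles)
  cmax <- regionPeaks(sampleProfile)
  fr <- coverageFractions(M, cmax, seq_along(angles))
  names(fr) <- names(regionFits(sampleProfile))
  new("ViewSetScore", angles = angles, perRegion = pmin(pmax(fr, 0), 1),
      meanCoverage = mean(fr), method = method)
}

#' Select the optimal set of imaging angles
#'
#' \code{method = "exhaustive"} enumerates every n-subset of the candidate
#' grid and returns the one with the highest mean coverage (the combination
#' used for imaging); ties are broken deterministically by maximal minimum
#' pairwise angular spacing, then lexicographically. Guarded at 10^6
#' combinations -- beyond that, use greedy. \code{method = "greedy"} starts
#' from the single best angle and adds the angle with the largest marginal
#' mean-coverage gain until n angles are chosen, with the same tie-break.
#'
#' @param sampleProfile a \linkS4class{SampleProfile}.
#' @param n number of views to select.
#' @param candidates candidate angles in degrees; defaults to the angles the
#'   profile was measured at. Any angle can be scored: prediction uses the
#'   fitted curves, not the raw samples.
#' @param method "exhaustive" (default) or "greedy".
#' @return a \linkS4class{ViewSetScore}.
#' @export
selectViews <- function(sampleProfile, n, candidates = NULL,
                        method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  if (is.null(candidates)) candidates <- sampleProfile@viewAngles
  candidates <- sort(wrapDeg(candidates))
  if (anyDuplicated(candidates)) stop("candidate angles must be distinct")
  if (n > length(candidates)) stop("n exceeds the number of candidates")
  M <- responseMatrix(sampleProfile, candidates)
  cmax <- regionPeaks(sampleProfile)
  scoreCols <- function(cols) mean(coverageFractions(M, cmax, cols))
  if (method == "exhaustive") {
    if (choose(length(candidates), n) > 1e6)
      stop("more than 1e6 combinations; use method = \"greedy\"")
    combos <- utils::combn(length(candidates), n)
    scores <- apply(combos, 2, scoreCols)
    bestScore <- max(scores)
    tied <- which(scores >= bestScore - 1e-12)
    if (length(tied) > 1L) {
      sp <- vapply(tied, function(j) minSpacing(candidates[combos[, j]]), numeric(1))
      tied <- tied[sp >= max(sp) - 1e-9]
      if (length(tied) > 1L) {       # lexicographic on the sorted angle vectors
        key <- vapply(tied, function(j)
          paste(sprintf("%08.3f", sort(candidates[combos[, j]])), collapse = ","),
          character(1))
        tied <- tied[order(key)][1L]
      }
    }
    cols <- combos[, tied[1L]]
  } else {
    cols <- integer(0)
    for (k in seq_len(n)) {
      rest <- setdiff(seq_along(candidates), cols)
      gains <- vapply(rest, function(j) scoreCols(c(cols, j)), numeric(1))
      best <- max(gains)
      tied <- rest[gains >= best - 1e-12]
      if (length(tied) > 1L) {
        sp <- vapply(tied, function(j) minSpacing(candidates[c(cols, j)]), numeric(1))
        tied <- tied[sp >= max(sp) - 1e-9]
        tied <- tied[order(candidates[tied])]
      }
      cols <- c(cols, tied[1L])
    }
    cols <- sort(cols)
  }
  fr <- coverageFractions(M, cmax, cols)
  names(fr) <- names(regionFits(sampleProfile))
  new("ViewSetScore", angles = candidates[cols],
      perRegion = pmin(pmax(fr, 0), 1), meanCoverage = mean(fr),
      method = method)
}

#' Update a sample profile with freshly acquired views
#'
#' The time-lapse update step: samples at the re-acquired angles are replaced
#' in every region's response profile and all fits are recomputed; views not
#' re-acquired keep their stored samples. A new angle absent from the stored
#' grid is snapped to the nearest stored angle with a warning.
#'
#' @param sampleProfile the current \linkS4class{SampleProfile}.
#' @param newProfiles data.frame from \code{\link{buildProfiles}} run on the
#'   newly acquired views only.
#' @return the updated \linkS4class{SampleProfile}; attribute
#'   \code{viewsReplaced} lists the substituted angles.
#' @export
updateSampleProfile <- function(sampleProfile, newProfiles) {
  prof <- profileTable(sampleProfile)
  stored <- sampleProfile@viewAngles
  newAngles <- unique(wrapDeg(newProfiles$view_angle_deg))
  replaced <- numeric(0)
  for (a in newAngles) {
    target <- a
    if (!any(abs(circDiffDeg(stored, a)) < 1e-6)) {
      target <- stored[which.min(circDistDeg(stored, a))]
      warning(sprintf("angle %.2f deg not on the stored grid; snapped to %.2f deg",
                      a, target))
    }
    sub <- newProfiles[wrapDeg(newProfiles$view_angle_deg) == a, ]
    sub$view_angle_deg <- target
    prof <- prof[wrapDeg(prof$view_angle_deg) != target, ]
    prof <- rbind(prof, sub)
    replaced <- c(replaced, target)
  }
  prof <- prof[order(prof$region_start_deg, prof$view_angle_deg), ]
  rownames(prof) <- NULL
  out <- fitSampleProfile(prof, binWidth = sampleProfile@binWidth,
                          background = sampleProfile@background,
                          meta = sampleProfile@meta)
  attr(out, "viewsReplaced") <- replaced
  out
}
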
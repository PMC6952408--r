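# From registered entropy projections to per-view foreground counts binned by
# azimuth: the measured sample response profile C_alpha(x).

#' Calibrate the background entropy level from a blank image
#'
#' The spectral-entropy scale is not absolute: noise level and exposure shift
#' the whole entropy profile, so foreground calling uses a predetermined
#' background level approximated by the entropy of a blank (sample-free)
#' image. The blank is pushed through the same pipeline as the data it
#' calibrates (for stacks: per-plane entropy then minimum projection along
#' the rotation axis), and the level is a low percentile of its non-empty
#' block entropies minus a safety margin. Structured content concentrates the
#' DCT spectrum, so foreground blocks fall BELOW this level.
#'
#' @param blank numeric matrix, 3D array or \linkS4class{SpimView} containing
#'   no sample signal (noise only).
#' @param blockSize,stride tiling parameters (see \code{\link{entropyMap}}).
#' @param percentile lower quantile of blank entropies used as the level
#'   (default 0.05).
#' @param margin subtracted safety margin in nats (default 0).
#' @return the background level in nats, with attributes \code{percentile},
#'   \code{margin} and \code{nBlocks}.
#' @export
calibrateBackground <- function(blank, blockSize = 16L, stride = blockSize,
                                percentile = 0.05, margin = 0) {
  if (is(blank, "SpimView")) blank <- stackArray(blank)
  em <- entropyMap(blank, blockSize = blockSize, stride = stride)
  v <- em@values
  if (length(dim(v)) == 3L) {
    big <- ifelse(em@empty | is.na(v), Inf, v)
    mn <- big[, 1L, ]
    if (dim(v)[2L] > 1L) for (j in 2:dim(v)[2L]) mn <- pmin(mn, big[, j, ])
    vals <- mn[is.finite(mn)]
  } else {
    vals <- v[!em@empty & !is.na(v)]
  }
  if (length(vals) == 0L)
    stop("the blank contains no non-empty blocks; supply a noise-bearing blank image")
  level <- as.numeric(stats::quantile(vals, percentile)) - margin
  structure(level, percentile = percentile, margin = margin,
            nBlocks = length(vals))
}

#' Foreground mask of a (warped) entropy projection
#'
#' A non-empty cell is foreground iff its entropy lies strictly below the
#' calibrated background level; empty cells are never foreground.
#'
#' @param warped list with \code{values} and \code{empty} (output of
#'   \code{\link{warpEntropy}}), or a \linkS4class{ViewProjection}.
#' @param background level in nats from \code{\link{calibrateBackground}}.
#' @return list with \code{mask} (logical matrix) and \code{count}.
#' @export
foregroundMask <- function(warped, background) {
  if (is(warped, "ViewProjection"))
    warped <- list(values = warped@entropy, empty = warped@empty)
  mask <- !warped$empty & !is.na(warped$values) & warped$values < background
  list(mask = mask, count = sum(mask))
}

#' Bin foreground cells by azimuth about the rotation-axis centre
#'
#' Each foreground cell is assigned to the half-open angular bin of its
#' centre's azimuth, measured counterclockwise from +x in the registered
#' reference frame. The bin total over all regions equals the foreground
#' count. Cells exactly at the centre are assigned to azimuth 0 (logged).
#'
#' @param mask logical foreground matrix on the (x-block, z-plane) grid.
#' @param blockSize block edge in pixels of the x axis of the grid.
#' @param center rotation-axis centre (x, z) in pixel coordinates of the
#'   underlying projection.
#' @param binWidth bin width in degrees; must divide 360 (default 10).
#' @param stride tile step of the x-block grid (defaults to blockSize).
#' @return named integer vector of counts, one per bin start angle.
#' @export
binByAngle <- function(mask, blockSize, center, binWidth = 10,
                       stride = blockSize) {
  if (360 %% binWidth != 0) stop("360 must be divisible by binWidth")
  b <- as.numeric(blockSize)
  nb <- nrow(mask); nz <- ncol(mask)
  cx <- (seq_len(nb) - 1) * as.numeric(stride) + (b + 1) / 2 - center[1]
  cz <- seq_len(nz) - center[2]
  X <- matrix(cx, nb, nz); Z <- matrix(cz, nb, nz, byrow = TRUE)
  starts <- seq(0, 360 - binWidth, by = binWidth)
  xs <- X[mask]; zs <- Z[mask]
  atCenter <- xs == 0 & zs == 0
  if (any(atCenter))
    message(sprintf("binByAngle: %d cell(s) at the rotation centre assigned to azimuth 0",
                    sum(atCenter)))
  phi <- wrapDeg(radToDeg(atan2(zs, xs)))
  phi[atCenter] <- 0
  counts <- as.integer(table(factor(floor(phi / binWidth) * binWidth, levels = starts)))
  names(counts) <- starts
  counts
}

#' Build per-region sample response profiles
#'
#' For every registered view: warp its entropy min-projection into the
#' reference frame, call foreground against the background level, and bin the
#' foreground cells by azimuth. The result is the measured response
#' C_alpha(x): foreground cells of angular region alpha as a function of
#' imaging angle x.
#'
#' @param projections list of \linkS4class{ViewProjection}.
#' @param transforms named list of \linkS4class{RigidTransform2D} from
#'   \code{\link{registerViews}}; views lacking a transform are excluded with
#'   a message.
#' @param background calibrated background level (nats).
#' @param binWidth angular bin width in degrees (default 10).
#' @return data.frame with columns \code{region_start_deg},
#'   \code{view_angle_deg}, \code{foreground_blocks}; attribute
#'   \code{viewsProcessed} records how many views were analysed.
#' @export
buildProfiles <- function(projections, transforms, background, binWidth = 10) {
  rows <- list()
  processed <- 0L
  for (proj in projections) {
    key <- as.character(viewAngle(proj))
    tf <- transforms[[key]]
    if (is.null(tf)) {
      message(sprintf("buildProfiles: view %s deg has no transform; excluded", key))
      next
    }
    w <- warpEntropy(proj, tf)
    fg <- foregroundMask(w, background)
    counts <- binByAngle(fg$mask, blockSize(proj), tf@center, binWidth,
                         stride = proj@stride)
    rows[[length(rows) + 1L]] <- data.frame(
      region_start_deg = as.numeric(names(counts)),
      view_angle_deg = viewAngle(proj),
      foreground_blocks = counts, row.names = NULL)
    processed <- processed + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_start_deg = numeric(), view_angle_deg = numeric(),
               foreground_blocks = integer())
  attr(out, "viewsProcessed") <- processed
  out
}

#' Measured union coverage of a set of views
#'
#' Counts the grid cells that are foreground in at least one of the chosen
#' views (after warping into the reference frame) -- the measured, not
#' predicted, sample coverage of an angle set. Used to validate predicted
#' selections against what the chosen views actually deliver.
#'
#' @param projections list of \linkS4class{ViewProjection} (all views).
#' @param transforms named transforms from \code{\link{registerViews}}.
#' @param background calibrated background level (nats).
#' @param angles the view angles making up the set.
#' @return number of distinct foreground cells, with attribute
#'   \code{perView} (individual counts).
#' @export
unionCoverage <- function(projections, transforms, background, angles) {
  angs <- vapply(projections, viewAngle, numeric(1))
  acc <- NULL
  per <- numeric(0)
  for (a in angles) {
    i <- which(abs(circDiffDeg(angs, a)) < 1e-6)
    if (length(i) != 1L) stop(sprintf("no acquired view at %.1f deg", a))
    tf <- transforms[[as.character(angs[i])]]
    fg <- foregroundMask(warpEntropy(projections[[i]], tf), background)
    per <- c(per, fg$count)
    acc <- if (is.null(acc)) fg$mask else acc | fg$mask
  }
  structure(sum(acc), perView = per)
}
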
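# Registration of per-view projections into the 0-degree sample-fixed frame.
# The stage angle is known and trusted, so the default engine rotates by the
# nominal angle (an optional refinement window exists for stages with
# backlash) and recovers the remaining translation by phase correlation. A lightweight feature engine
# (blob centroids + mutual nearest-neighbour matching + least-squares rigid
# estimation) is available as an alternative.

#' Construct a 2D rigid transform
#'
#' @param rotation rotation in degrees.
#' @param tx,tz translation in pixels.
#' @param center centre of rotation (x, z) in pixel coordinates.
#' @param residual normalised residual score (see class docs).
#' @param flags character vector of flags.
#' @return a \linkS4class{RigidTransform2D} mapping p to
#'   R(rotation) (p - center) + center + (tx, tz).
#' @export
rigidTransform2D <- function(rotation, tx = 0, tz = 0, center = c(0, 0),
                             residual = NA_real_, flags = character()) {
  new("RigidTransform2D", rotation = wrapDeg(rotation), tx = tx, tz = tz,
      center = as.numeric(center), residual = residual, flags = flags)
}

#' Apply, compose and invert rigid transforms
#'
#' \code{transformPoints} maps moving-frame points into the reference frame;
#' \code{composeTransforms(a, b)} returns the transform applying \code{b}
#' first, then \code{a}; \code{invertTransform} reverses a transform.
#' Composing a transform with its inverse yields the identity to numerical
#' precision.
#'
#' @param tf,a,b \linkS4class{RigidTransform2D} objects (\code{a} and \code{b}
#'   must share their centre of rotation).
#' @param pts numeric matrix (n x 2) of (x, z) pixel coordinates.
#' @return transformed points, or a composed/inverted transform.
#' @export
transformPoints <- function(tf, pts) {
  th <- degToRad(tf@rotation)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, tf@center) %*% t(R), 2, tf@center + c(tf@tx, tf@tz), `+`)
}

#' @rdname transformPoints
#' @export
composeTransforms <- function(a, b) {
  stopifnot(max(abs(a@center - b@center)) < 1e-9)
  th <- degToRad(a@rotation)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t2 <- as.numeric(R %*% c(b@tx, b@tz)) + c(a@tx, a@tz)
  res <- c(a@residual, b@residual)
  res <- if (any(!is.na(res))) max(res, na.rm = TRUE) else NA_real_
  rigidTransform2D(a@rotation + b@rotation, t2[1], t2[2], a@center,
                   residual = res, flags = union(a@flags, b@flags))
}

#' @rdname transformPoints
#' @export
invertTransform <- function(tf) {
  th <- degToRad(-tf@rotation)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t2 <- -as.numeric(R %*% c(tf@tx, tf@tz))
  rigidTransform2D(-tf@rotation, t2[1], t2[2], tf@center,
                   residual = tf@residual, flags = tf@flags)
}

# Bilinear rotation of an image about `center` (pixel coords); zero outside.
rotateImage <- function(img, deg, center = (dim(img) + 1) / 2) {
  d <- dim(img)
  th <- degToRad(-deg)                   # inverse map for output sampling
  gx <- rep(seq_len(d[1]), d[2]) - center[1]
  gz <- rep(seq_len(d[2]), each = d[1]) - center[2]
  sx <- gx * cos(th) - gz * sin(th) + center[1]
  sz <- gx * sin(th) + gz * cos(th) + center[2]
  bilinearSample(img, sx, sz, d)
}

bilinearSample <- function(img, sx, sz, dOut) {
  d <- dim(img)
  x0 <- floor(sx); z0 <- floor(sz)
  fx <- sx - x0; fz <- sz - z0
  val <- numeric(length(sx))
  ok <- x0 >= 1 & x0 + 1 <= d[1] & z0 >= 1 & z0 + 1 <= d[2]
  i00 <- cbind(x0[ok], z0[ok]); i10 <- cbind(x0[ok] + 1, z0[ok])
  i01 <- cbind(x0[ok], z0[ok] + 1); i11 <- cbind(x0[ok] + 1, z0[ok] + 1)
  val[ok] <- img[i00] * (1 - fx[ok]) * (1 - fz[ok]) +
    img[i10] * fx[ok] * (1 - fz[ok]) +
    img[i01] * (1 - fx[ok]) * fz[ok] +
    img[i11] * fx[ok] * fz[ok]
  matrix(val, dOut[1], dOut[2])
}

# warp an image by a rigid transform (inverse mapping, bilinear); NA outside
warpImage <- function(img, tf) {
  d <- dim(img)
  inv <- invertTransform(tf)
  pts <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  src <- transformPoints(inv, pts)
  out <- bilinearSample(img, src[, 1], src[, 2], d)
  outside <- src[, 1] < 1 | src[, 1] > d[1] | src[, 2] < 1 | src[, 2] > d[2]
  out[matrix(outside, d[1], d[2])] <- NA
  out
}

# Phase correlation: translation (dx, dz) such that shifting `mov` by it
# aligns to `ref`, with 3-point parabolic sub-pixel refinement. The peak
# search is restricted to |shift| <= maxShift per axis: the rotation axis is
# approximately centred by construction, so large shifts are artefacts of
# the camera-fixed illumination/detection pattern, not sample motion.
phaseCorrelate <- function(ref, mov, maxShift = 16) {
  d <- dim(ref)
  Fa <- stats::fft(ref); Fb <- stats::fft(mov)
  cp <- Fa * Conj(Fb)
  cp <- cp / (Mod(cp) + 1e-12)
  surf <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)
  sh1 <- (seq_len(d[1]) - 1 + d[1] / 2) %% d[1] - d[1] / 2
  sh2 <- (seq_len(d[2]) - 1 + d[2] / 2) %% d[2] - d[2] / 2
  allowed <- outer(abs(sh1) <= maxShift, abs(sh2) <= maxShift, `&`)
  masked <- ifelse(allowed, surf, -Inf)
  pk <- arrayInd(which.max(masked), d)
  sub <- function(i, n) (i - 1 + n / 2) %% n - n / 2    # wrap to signed
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (abs(den) < 1e-12) 0 else 0.5 * (m1 - p1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dx <- para(surf[wrap(pk[1] - 1, d[1]), pk[2]], surf[pk[1], pk[2]],
             surf[wrap(pk[1] + 1, d[1]), pk[2]])
  dz <- para(surf[pk[1], wrap(pk[2] - 1, d[2])], surf[pk[1], pk[2]],
             surf[pk[1], wrap(pk[2] + 1, d[2])])
  list(shift = c(sub(pk[1], d[1]) + dx, sub(pk[2], d[2]) + dz),
       peak = surf[pk[1], pk[2]])
}

nccOverlap <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(0)
  suppressWarnings(cc <- stats::cor(a[ok], b[ok]))
  if (is.na(cc)) 0 else cc
}

residualScore <- function(ref, warped) {
  ok <- is.finite(ref) & is.finite(warped)
  if (!any(ok)) return(NA_real_)
  mean(abs(ref[ok] - warped[ok])) / (mean(abs(ref[ok])) + 1e-12)
}

# simple blob features: local maxima of a lightly smoothed image
blobFeatures <- function(img, nMax = 60L) {
  k <- matrix(1 / 9, 3, 3)
  d <- dim(img)
  sm <- img
  sm[2:(d[1] - 1), 2:(d[2] - 1)] <-
    (img[1:(d[1] - 2), 1:(d[2] - 2)] + img[1:(d[1] - 2), 2:(d[2] - 1)] + img[1:(d[1] - 2), 3:d[2]] +
     img[2:(d[1] - 1), 1:(d[2] - 2)] + img[2:(d[1] - 1), 2:(d[2] - 1)] + img[2:(d[1] - 1), 3:d[2]] +
     img[3:d[1], 1:(d[2] - 2)] + img[3:d[1], 2:(d[2] - 1)] + img[3:d[1], 3:d[2]]) / 9
  core <- sm[3:(d[1] - 2), 3:(d[2] - 2)]
  isMax <- core >= sm[2:(d[1] - 3), 3:(d[2] - 2)] & core >= sm[4:(d[1] - 1), 3:(d[2] - 2)] &
    core >= sm[3:(d[1] - 2), 2:(d[2] - 3)] & core >= sm[3:(d[1] - 2), 4:(d[2] - 1)] &
    core > stats::quantile(sm, 0.9)
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  pts <- cbind(idx[, 1] + 2, idx[, 2] + 2, core[isMax])
  pts[order(-pts[, 3]), , drop = FALSE][seq_len(min(nMax, nrow(pts))), , drop = FALSE]
}

registerFeature <- function(ref, mov, nominalDeltaDeg, center) {
  fr <- blobFeatures(ref); rot <- rotateImage(mov, nominalDeltaDeg, center)
  fm <- blobFeatures(rot)
  if (nrow(fr) < 3 || nrow(fm) < 3) return(NULL)
  # mutual nearest neighbours after nominal rotation
  dmat <- outer(fr[, 1], fm[, 1], `-`)^2 + outer(fr[, 2], fm[, 2], `-`)^2
  jr <- apply(dmat, 1, which.min); jm <- apply(dmat, 2, which.min)
  mut <- which(jm[jr] == seq_len(nrow(fr)) & dmat[cbind(seq_len(nrow(fr)), jr)] < 15^2)
  if (length(mut) < 3) return(NULL)
  P <- fm[jr[mut], 1:2, drop = FALSE]    # moving (already nominally rotated)
  Q <- fr[mut, 1:2, drop = FALSE]        # reference
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) { sv$v[, 2] <- -sv$v[, 2]; R <- sv$v %*% t(sv$u) }
  extra <- radToDeg(atan2(R[2, 1], R[1, 1]))
  # translation of the residual rigid motion about `center`
  tvec <- cq - as.numeric(R %*% (cp - center)) - center
  list(rotation = nominalDeltaDeg + extra, shift = tvec)
}

#' Register one projection pair
#'
#' Estimates the rigid transform mapping \code{mov} into \code{ref}'s frame.
#' The default engine trusts the stage: it searches rotation only in a small
#' window around the nominal angle difference, scoring rotations by the phase
#' correlation peak, and recovers the translation from the correlation peak
#' with sub-pixel refinement. By default the rotation is fixed at the nominal
#' stage angle (\code{searchDeg = 0}): the stage is trusted, and refining the
#' rotation against image content can only inject error when the stage is
#' accurate. Set \code{searchDeg > 0} for stages with backlash. If the best warp scores below \code{sccFloor}
#' (normalised cross-correlation over the overlap) the pair is declared
#' featureless and the nominal stage transform is returned flagged
#' "nominal-only". Disagreement with the stage beyond \code{searchDeg} is an
#' error: the stage is trusted.
#'
#' @param ref,mov numeric matrices (same shape): reference and moving
#'   maximum-intensity projections.
#' @param nominalDeltaDeg nominal angle difference from stage metadata
#'   (degrees; rotation taking mov into ref).
#' @param engine "phasecorr" (default) or "feature".
#' @param searchDeg half-width of the rotation refinement window in degrees
#'   (default 0: rotation fixed at the nominal stage angle).
#' @param center centre of rotation in pixels; defaults to the image centre.
#' @param sccFloor NCC floor below which the pair is featureless (default 0.2).
#' @param maxShift largest admissible translation in pixels (default 16); the
#'   sample sits near the rotation axis, so larger shifts indicate the
#'   correlation locked onto the camera-fixed degradation pattern.
#' @return a \linkS4class{RigidTransform2D}.
#' @export
registerProjectionPair <- function(ref, mov, nominalDeltaDeg,
                                   engine = c("phasecorr", "feature"),
                                   searchDeg = 0, center = NULL,
                                   sccFloor = 0.2, maxShift = 16) {
  engine <- match.arg(engine)
  stopifnot(identical(dim(ref), dim(mov)))
  if (is.null(center)) center <- (dim(ref) + 1) / 2
  nominal <- rigidTransform2D(nominalDeltaDeg, 0, 0, center,
                              residual = NA_real_, flags = "nominal-only")
  cand <- NULL
  if (engine == "feature") {
    fe <- registerFeature(ref, mov, nominalDeltaDeg, center)
    if (!is.null(fe))
      cand <- rigidTransform2D(fe$rotation, fe$shift[1], fe$shift[2], center)
  } else {
    evalRot <- function(deg) {
      pc <- phaseCorrelate(ref, rotateImage(mov, deg, center), maxShift = maxShift)
      list(deg = deg, shift = pc$shift, peak = pc$peak)
    }
    if (searchDeg > 0) {
      coarse <- lapply(seq(nominalDeltaDeg - searchDeg, nominalDeltaDeg + searchDeg,
                           by = 0.5), evalRot)
      pk <- vapply(coarse, `[[`, numeric(1), "peak")
      best <- coarse[[which.max(pk)]]
      fine <- lapply(seq(best$deg - 0.5, best$deg + 0.5, by = 0.1), evalRot)
      pkf <- vapply(fine, `[[`, numeric(1), "peak")
      i <- which.max(pkf)
      # parabolic refinement of rotation on the peak-vs-angle curve
      deg <- fine[[i]]$deg
      if (i > 1 && i < length(fine)) {
        den <- pkf[i - 1] - 2 * pkf[i] + pkf[i + 1]
        if (abs(den) > 1e-12) deg <- deg + 0.1 * 0.5 * (pkf[i - 1] - pkf[i + 1]) / den
      }
      final <- evalRot(deg)
    } else {
      final <- evalRot(nominalDeltaDeg)
    }
    cand <- rigidTransform2D(final$deg, final$shift[1], final$shift[2], center)
  }
  if (is.null(cand)) return(nominal)
  if (circDistDeg(cand@rotation, nominalDeltaDeg) > searchDeg + 0.5)
    stop(sprintf("recovered rotation %.2f deg disagrees with the stage (%.2f deg)",
                 cand@rotation, wrapDeg(nominalDeltaDeg)))
  warped <- warpImage(mov, cand)
  score <- nccOverlap(ref, warped)
  # the stage transform is a strong prior: a refinement that aligns worse
  # than the unrefined nominal is spurious and is discarded
  nomWarped <- warpImage(mov, rigidTransform2D(nominalDeltaDeg, 0, 0, center))
  nomScore <- nccOverlap(ref, nomWarped)
  if (score < sccFloor || score < nomScore) {
    nominal@residual <- residualScore(ref, nomWarped)
    return(nominal)
  }
  cand@residual <- residualScore(ref, warped)
  cand
}

#' Register all views into the 0-degree frame
#'
#' Registers raw maximum-intensity projections (never entropy maps). In
#' "direct" mode every view is registered straight to the reference view,
#' seeded by its full nominal stage angle; in "chain" mode successive pairs
#' are registered and composed, which accumulates less per-pair rotation but
#' compounds errors. Pairs flagged "nominal-only" are kept and reported.
#'
#' @param projections list of \linkS4class{ViewProjection} objects with
#'   distinct angles; the view closest to 0 degrees is the reference.
#' @param mode "direct" (default) or "chain".
#' @param engine,searchDeg,center,sccFloor passed to
#'   \code{\link{registerProjectionPair}}.
#' @return named list of \linkS4class{RigidTransform2D}, one per view angle
#'   (names = angle), each mapping that view into the reference frame.
#' @export
registerViews <- function(projections, mode = c("direct", "chain"),
                          engine = "phasecorr", searchDeg = 0, center = NULL,
                          sccFloor = 0.2) {
  mode <- match.arg(mode)
  angs <- vapply(projections, viewAngle, numeric(1))
  if (anyDuplicated(wrapDeg(angs))) stop("view angles must be distinct")
  refIdx <- which.min(circDistDeg(angs, 0))
  if (is.null(center)) center <- (dim(projections[[refIdx]]@rawMip) + 1) / 2
  out <- vector("list", length(projections))
  names(out) <- as.character(angs)
  out[[refIdx]] <- rigidTransform2D(0, 0, 0, center, residual = 0)
  if (length(projections) == 1L) return(out)
  refMip <- projections[[refIdx]]@rawMip
  refAng <- angs[refIdx]
  if (mode == "direct") {
    for (i in seq_along(projections)) {
      if (i == refIdx) next
      # a sample point seen at p in view a sits at R(a - a_ref) p in the ref view
      out[[i]] <- registerProjectionPair(refMip, projections[[i]]@rawMip,
                                         angs[i] - refAng, engine = engine,
                                         searchDeg = searchDeg, center = center,
                                         sccFloor = sccFloor)
    }
  } else {
    # walk the angle-sorted ring starting at the reference, composing pairs
    ordAng <- order(angs)
    pos <- match(refIdx, ordAng)
    ring <- ordAng[((pos - 1 + seq_len(length(ordAng) - 1)) %% length(ordAng)) + 1]
    acc <- out[[refIdx]]
    prev <- refIdx
    for (j in ring) {
      tf <- registerProjectionPair(projections[[prev]]@rawMip,
                                   projections[[j]]@rawMip,
                                   angs[j] - angs[prev], engine = engine,
                                   searchDeg = searchDeg, center = center,
                                   sccFloor = sccFloor)
      acc <- composeTransforms(acc, tf)
      out[[j]] <- acc
      prev <- j
    }
  }
  nOnly <- sum(vapply(out, function(t) "nominal-only" %in% t@flags, logical(1)))
  if (nOnly > 0)
    message(sprintf("registerViews: %d pair(s) fell back to the nominal stage transform", nOnly))
  out
}

#' Estimate the rotation-axis centre from projections
#'
#' Coarse-to-fine grid search for the in-plane centre of rotation: candidate
#' centres are scored by the correlation achieved when rotating views onto
#' the reference by their nominal angles.
#'
#' @param projections list of \linkS4class{ViewProjection}; at least 2.
#' @param span half-width of the search window in pixels (default 10).
#' @return centre (x, z) in pixel coordinates.
#' @export
estimateRotationCenter <- function(projections, span = 10) {
  stopifnot(length(projections) >= 2L)
  angs <- vapply(projections, viewAngle, numeric(1))
  refIdx <- which.min(circDistDeg(angs, 0))
  ref <- projections[[refIdx]]@rawMip
  others <- setdiff(seq_along(projections), refIdx)
  use <- others[order(-circDistDeg(angs[others], angs[refIdx]))]
  use <- use[seq_len(min(3L, length(use)))]
  c0 <- (dim(ref) + 1) / 2
  scoreCenter <- function(cc) {
    s <- 0
    for (i in use) {
      delta <- circDiffDeg(angs[i], angs[refIdx])  # rotation taking view i -> ref
      s <- s + nccOverlap(ref, rotateImage(projections[[i]]@rawMip, delta, cc))
    }
    s
  }
  best <- c0
  for (step in c(4, 1)) {
    grid <- expand.grid(x = best[1] + seq(-span, span, by = step),
                        z = best[2] + seq(-span, span, by = step))
    sc <- apply(grid, 1, scoreCenter)
    best <- as.numeric(grid[which.max(sc), ])
    span <- step
  }
  best
}

#' Warp an entropy min-projection into the reference frame
#'
#' Entropy values live on a block grid; they are resampled by nearest
#' neighbour on block centres (interpolation would blur the foreground
#' decision). Empty flags propagate; cells mapping outside the source field
#' become empty.
#'
#' @param proj a \linkS4class{ViewProjection}.
#' @param tf \linkS4class{RigidTransform2D} mapping this view into the
#'   reference frame (pixel coordinates of the raw projection).
#' @return list with \code{values} and \code{empty}, the warped entropy grid.
#' @export
warpEntropy <- function(proj, tf) {
  ent <- proj@entropy; emp <- proj@empty
  b <- as.numeric(proj@blockSize); s <- as.numeric(proj@stride)
  nb <- nrow(ent); nz <- ncol(ent)
  # pixel coords of cell centres: x on the block grid, z at plane resolution
  cx <- (seq_len(nb) - 1) * s + (b + 1) / 2
  cz <- seq_len(nz)
  pts <- cbind(rep(cx, nz), rep(cz, each = nb))
  src <- transformPoints(invertTransform(tf), pts)
  bi <- round((src[, 1] - (b + 1) / 2) / s) + 1
  zi <- round(src[, 2])
  ok <- bi >= 1 & bi <= nb & zi >= 1 & zi <= nz
  vals <- matrix(NA_real_, nb, nz)
  empty <- matrix(TRUE, nb, nz)
  idx <- cbind(bi[ok], zi[ok])
  vals[ok] <- ent[idx]
  empty[ok] <- emp[idx]
  list(values = vals, empty = empty)
}

#' Serialize and restore view transforms
#'
#' JSON round trip of a named transform set from \code{\link{registerViews}}:
#' one record per view with angle, rotation, translation, centre, residual
#' and flags.
#'
#' @param transforms named list of \linkS4class{RigidTransform2D}.
#' @param path JSON file path.
#' @return \code{readTransforms} returns the restored named list.
#' @export
writeTransforms <- function(transforms, path) {
  recs <- lapply(names(transforms), function(nm) {
    tf <- transforms[[nm]]
    list(angle = as.numeric(nm), rotation_deg = tf@rotation, tx = tf@tx,
         tz = tf@tz, center = tf@center, residual = tf@residual,
         flags = as.list(tf@flags))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- lapply(recs, function(r) {
    fl <- unlist(r$flags)
    rigidTransform2D(r$rotation_deg, r$tx, r$tz, unlist(r$center),
                     residual = r$residual %||% NA_real_,
                     flags = if (length(fl)) as.character(fl) else character())
  })
  names(out) <- vapply(recs, function(r) as.character(r$angle), character(1))
  out
}
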
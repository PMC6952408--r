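# Information-content metric: block-wise Shannon entropy of the normalised
# 2D DCT-II power spectrum. A structured block concentrates spectral power in
# few coefficients (low entropy); a noise block spreads it (high entropy).

# Orthonormal DCT-II basis matrix: D[u, i] = w(u) cos(pi u (2i + 1) / (2N)),
# w(0) = sqrt(1/N), w(u>0) = sqrt(2/N). F = D X t(D); t(D) D = I.
dctMatrix <- function(n) {
  u <- 0:(n - 1L)
  D <- sqrt(2 / n) * cos(pi * outer(u, 2L * u + 1L) / (2 * n))
  D[1L, ] <- sqrt(1 / n)
  D
}

#' 2D DCT-II of a square image patch
#'
#' Transforms a patch into the cosine frequency domain using the orthonormal
#' DCT-II convention, under which Parseval's identity holds (the summed squared
#' coefficients equal the summed squared intensities).
#'
#' @param patch square numeric matrix of non-negative intensities, at least 2x2.
#' @return list with \code{coef} (the N x N DCT-II coefficients), \code{power}
#'   (coef^2 / N^2), \code{p} (power normalised to sum 1, or all zero for an
#'   empty patch) and \code{empty} (TRUE when total spectral power is zero).
#' @examples
#' s <- dct2Patch(matrix(1, 8, 8))
#' s$coef[1, 1]   # DC term = N * mean for a constant patch
#' @export
dct2Patch <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch) || nrow(patch) < 2L)
    stop("patch must be a square matrix with edge >= 2")
  n <- nrow(patch)
  D <- dctMatrix(n)
  coef <- D %*% patch %*% t(D)
  power <- coef^2 / n^2
  tot <- sum(power)
  list(coef = coef, power = power,
       p = if (tot > 0) power / tot else power * 0,
       empty = tot == 0)
}

#' Spectral entropy of a DCT spectrum
#'
#' Shannon entropy (nats) of the normalised DCT-II power spectrum,
#' \eqn{S = -\sum p \ln p} with \eqn{0 \ln 0 := 0}. The normalisation cancels
#' any positive intensity scaling of the source patch. An all-zero (empty)
#' spectrum yields 0 with attribute \code{empty = TRUE}; a dark patch carries
#' no information and is flagged rather than scored.
#'
#' @param spectrum output of \code{\link{dct2Patch}}, or a square numeric
#'   matrix (transformed first).
#' @return entropy in nats, in [0, 2 log N]; attribute \code{empty}.
#' @export
spectralEntropy <- function(spectrum) {
  if (is.matrix(spectrum)) spectrum <- dct2Patch(spectrum)
  if (isTRUE(spectrum$empty)) return(structure(0, empty = TRUE))
  p <- spectrum$p
  p <- p[p > 0]
  structure(-sum(p * log(p)), empty = FALSE)
}

# Entropy of every block of one non-overlapping tiling: a block-diagonal DCT
# operator turns the whole plane transform into two dense matrix products.
entropyTiling <- function(plane, blockSize, intensityFloor = 0) {
  nx <- nrow(plane); ny <- ncol(plane)
  nbx <- nx %/% blockSize; nby <- ny %/% blockSize
  D <- dctMatrix(blockSize)
  mkOp <- function(nb) {
    M <- matrix(0, nb * blockSize, nb * blockSize)
    for (b in seq_len(nb)) {
      i <- (b - 1L) * blockSize
      M[i + 1:blockSize, i + 1:blockSize] <- D
    }
    M
  }
  ux <- nbx * blockSize; uy <- nby * blockSize
  sub <- plane[seq_len(ux), seq_len(uy), drop = FALSE]
  F2 <- (mkOp(nbx) %*% sub %*% t(mkOp(nby)))^2
  bi <- (seq_len(ux) - 1L) %/% blockSize + 1L
  bj <- (seq_len(uy) - 1L) %/% blockSize + 1L
  grp <- bi[row(F2)] + nbx * (bj[col(F2)] - 1L)
  tot <- rowsum(as.vector(F2), grp)                     # per-block sum F^2
  plogp <- as.vector(F2) * log(pmax(as.vector(F2), 1e-300))
  sums <- rowsum(plogp, grp)
  itot <- rowsum(as.vector(sub), grp)
  # S = -sum (F2/tot) log(F2/tot) = log(tot) - sum(F2 log F2)/tot
  S <- ifelse(tot > 0, log(tot) - sums / tot, 0)
  em <- tot == 0 | itot <= intensityFloor
  list(values = matrix(ifelse(em, NA_real_, S), nbx, nby),
       empty = matrix(em, nbx, nby))
}

# Entropy of every block of one 2D plane at arbitrary stride. When the
# stride divides the block size the overlapping grid is the interleave of
# (blockSize/stride)^2 shifted non-overlapping tilings, each computed by the
# fast path; otherwise blocks are transformed one by one.
entropyPlane <- function(plane, blockSize, stride, intensityFloor = 0) {
  nx <- nrow(plane); ny <- ncol(plane)
  nbx <- (nx - blockSize) %/% stride + 1L
  nby <- (ny - blockSize) %/% stride + 1L
  vals <- matrix(NA_real_, nbx, nby)
  empty <- matrix(FALSE, nbx, nby)
  if (blockSize %% stride == 0L) {
    offs <- seq(0L, blockSize - 1L, by = stride)
    for (ox in offs) for (oy in offs) {
      r <- entropyTiling(plane[(1L + ox):nx, (1L + oy):ny, drop = FALSE],
                         blockSize, intensityFloor)
      ix <- (ox + (seq_len(nrow(r$values)) - 1L) * blockSize) / stride + 1L
      iy <- (oy + (seq_len(ncol(r$values)) - 1L) * blockSize) / stride + 1L
      ix <- ix[ix <= nbx]; iy <- iy[iy <= nby]
      vals[ix, iy] <- r$values[seq_along(ix), seq_along(iy)]
      empty[ix, iy] <- r$empty[seq_along(ix), seq_along(iy)]
    }
  } else {
    for (bj in seq_len(nby)) for (bi in seq_len(nbx)) {
      blk <- plane[(bi - 1L) * stride + 1:blockSize,
                   (bj - 1L) * stride + 1:blockSize]
      if (sum(blk) <= intensityFloor) { empty[bi, bj] <- TRUE; next }
      s <- spectralEntropy(dct2Patch(blk))
      if (attr(s, "empty")) empty[bi, bj] <- TRUE else vals[bi, bj] <- s
    }
  }
  list(values = vals, empty = empty)
}

#' Block-wise spectral-entropy map of an image or stack
#'
#' Tiles a 2D image (or each z-plane of a 3D stack) with square blocks and
#' computes the DCT-II spectral entropy of every block. Edge remainders that
#' do not fill a block are dropped; padding would inject artificial spectral
#' content. Stacks are encoded per z-plane in 2D. Runtime is linear in the
#' number of voxels.
#'
#' @param x numeric matrix, 3D array (x, y, z) or \linkS4class{SpimView}.
#' @param blockSize block edge in pixels (default 16).
#' @param stride tile step in pixels; defaults to \code{blockSize}
#'   (non-overlapping tiling).
#' @param intensityFloor blocks whose total intensity is at or below this
#'   floor are flagged empty (default 0).
#' @return an \linkS4class{EntropyMap}.
#' @export
entropyMap <- function(x, blockSize = 16L, stride = blockSize, intensityFloor = 0) {
  if (is(x, "SpimView")) x <- stackArray(x)
  blockSize <- as.integer(blockSize); stride <- as.integer(stride)
  if (blockSize < 2L || stride < 1L) stop("blockSize >= 2 and stride >= 1 required")
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("x must be a matrix or 3D array")
  if (d[1L] < blockSize || d[2L] < blockSize)
    stop("blockSize exceeds image extent (", paste(d, collapse = "x"), ")")
  if (length(d) == 2L) {
    r <- entropyPlane(x, blockSize, stride, intensityFloor)
    return(new("EntropyMap", values = as.array(r$values), empty = as.array(r$empty),
               blockSize = blockSize, stride = stride, sourceDim = as.integer(d)))
  }
  nbx <- (d[1L] - blockSize) %/% stride + 1L
  nby <- (d[2L] - blockSize) %/% stride + 1L
  vals <- array(NA_real_, c(nbx, nby, d[3L]))
  emp <- array(FALSE, c(nbx, nby, d[3L]))
  for (k in seq_len(d[3L])) {
    r <- entropyPlane(x[, , k], blockSize, stride, intensityFloor)
    vals[, , k] <- r$values
    emp[, , k] <- r$empty
  }
  new("EntropyMap", values = vals, empty = emp, blockSize = blockSize,
      stride = stride, sourceDim = as.integer(d))
}

#' Raw and entropy projections of a view along the rotation axis
#'
#' Collapses a view to the 2D objects the on-the-fly workflow registers and
#' thresholds: the maximum intensity projection of the raw stack along the
#' rotation axis (y), and the minimum intensity projection of the block
#' entropies on the matching (x-block, z-plane) grid. Empty blocks are ignored
#' by the minimum; a grid cell whose entire y-line is empty stays empty.
#'
#' @param view a \linkS4class{SpimView}.
#' @param emap the view's \linkS4class{EntropyMap}; computed on the fly when
#'   missing is not allowed -- run \code{\link{entropyMap}} first.
#' @return a \linkS4class{ViewProjection}.
#' @export
projectView <- function(view, emap) {
  stopifnot(is(view, "SpimView"))
  if (missing(emap) || is.null(emap))
    stop("no entropy map supplied; run entropyMap() on the view first")
  stopifnot(is(emap, "EntropyMap"))
  if (!identical(emap@sourceDim, as.integer(dim(view@stack))))
    stop("entropy map geometry does not match the view stack")
  raw <- mipAlongY(view@stack)
  v <- emap@values; e <- emap@empty
  dv <- dim(v)
  ent <- matrix(NA_real_, dv[1L], dv[3L])
  emp <- matrix(TRUE, dv[1L], dv[3L])
  big <- ifelse(e, Inf, ifelse(is.na(v), Inf, v))
  mn <- big[, 1L, ]
  if (dv[2L] > 1L) for (j in 2:dv[2L]) mn <- pmin(mn, big[, j, ])
  fin <- is.finite(mn)
  ent[fin] <- mn[fin]
  emp[fin] <- FALSE
  new("ViewProjection", angle = view@angle, rawMip = raw, entropy = ent,
      empty = emp, blockSize = emap@blockSize, stride = emap@stride,
      pitch = view@pitch)
}

#' Serialize and restore entropy maps
#'
#' Writes the entropy values as a 32-bit float TIFF (one page per z-plane
#' for stacks), the empty-block mask as a companion 8-bit TIFF, and a JSON
#' sidecar with the tiling geometry and the value scale. \code{readEntropyMap}
#' reverses the round trip.
#'
#' @param emap an \linkS4class{EntropyMap}.
#' @param path base path; \code{<path>.tif}, \code{<path>_empty.tif} and
#'   \code{<path>.json} are written.
#' @return the sidecar path, invisibly.
#' @export
writeEntropyMap <- function(emap, path) {
  v <- emap@values
  if (length(dim(v)) == 2L) { dim(v) <- c(dim(v), 1L) }
  e <- emap@empty
  if (length(dim(e)) == 2L) { dim(e) <- c(dim(e), 1L) }
  hi <- 2 * log(emap@blockSize)
  planes <- lapply(seq_len(dim(v)[3L]), function(k) {
    m <- v[, , k] / hi
    m[is.na(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(planes, paste0(path, ".tif"), bits.per.sample = 32L,
                  compression = "none")
  maskPlanes <- lapply(seq_len(dim(e)[3L]), function(k) (e[, , k]) * 1)
  tiff::writeTIFF(maskPlanes, paste0(path, "_empty.tif"),
                  bits.per.sample = 8L, compression = "none")
  side <- list(block_size = emap@blockSize, stride = emap@stride,
               source_dim = emap@sourceDim, value_scale = hi,
               values = basename(paste0(path, ".tif")),
               empty_mask = basename(paste0(path, "_empty.tif")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".json"))
}

#' @rdname writeEntropyMap
#' @export
readEntropyMap <- function(path) {
  path <- sub("\\.json$", "", path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vp <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  ep <- tiff::readTIFF(paste0(path, "_empty.tif"), all = TRUE)
  d3 <- length(vp)
  d <- c(dim(vp[[1]]), d3)
  vals <- array(NA_real_, d); emp <- array(FALSE, d)
  for (k in seq_len(d3)) {
    emp[, , k] <- ep[[k]] > 0.5
    m <- vp[[k]] * side$value_scale
    m[emp[, , k]] <- NA_real_
    vals[, , k] <- m
  }
  srcDim <- as.integer(side$source_dim)
  if (length(srcDim) == 2L) { vals <- vals[, , 1L]; emp <- emp[, , 1L] }
  new("EntropyMap", values = as.array(vals), empty = as.array(emp),
      blockSize = as.integer(side$block_size), stride = as.integer(side$stride),
      sourceDim = srcDim)
}
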
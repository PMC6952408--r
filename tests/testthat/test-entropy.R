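# DCT-II spectral-entropy metric: transform correctness against a direct
# double-sum oracle, entropy properties, block tiling and projections.

# Direct O(N^4) evaluation of the orthonormal 2D DCT-II, independent of the
# fast matrix-product implementation.
naiveDct2 <- function(X) {
  n <- nrow(X)
  w <- function(t) ifelse(t == 0, sqrt(1 / n), sqrt(2 / n))
  F <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0
    for (i in 0:(n - 1)) for (j in 0:(n - 1))
      s <- s + X[i + 1, j + 1] *
        cos(pi * u * (2 * i + 1) / (2 * n)) * cos(pi * v * (2 * j + 1) / (2 * n))
    F[u + 1, v + 1] <- w(u) * w(v) * s
  }
  F
}

test_that("fast DCT matches the direct double-sum oracle on patches up to 8x8", {
  set.seed(42)
  for (n in c(2L, 3L, 4L, 8L)) {
    for (rep in 1:5) {
      X <- matrix(runif(n * n, 0, 10), n, n)
      expect_lt(max(abs(dct2Patch(X)$coef - naiveDct2(X))), 1e-10)
    }
  }
  # the explicit tiny case: a single bright pixel in a 2x2 patch
  X <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_lt(max(abs(dct2Patch(X)$coef - naiveDct2(X))), 1e-12)
})

test_that("constant patch concentrates everything in the DC coefficient", {
  s <- dct2Patch(matrix(3, 8, 8))
  expect_equal(s$coef[1, 1], 8 * 3)
  expect_lt(max(abs(s$coef[-1])), 1e-12 * 3)
  expect_equal(as.numeric(spectralEntropy(s)), 0)
})

test_that("Parseval holds under the orthonormal convention", {
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rexp(64), 8, 8)
    s <- dct2Patch(X)
    expect_equal(sum(s$coef^2), sum(X^2), tolerance = 1e-9)
  }
})

test_that("spectral entropy is bounded, scale invariant, and maximal for a flat spectrum", {
  set.seed(11)
  for (rep in 1:20) {
    X <- matrix(runif(64), 8, 8)
    S <- as.numeric(spectralEntropy(dct2Patch(X)))
    expect_gte(S, 0)
    expect_lte(S, 2 * log(8) + 1e-12)
    for (c in c(0.5, 3, 1000))
      expect_equal(as.numeric(spectralEntropy(dct2Patch(c * X))), S,
                   tolerance = 1e-9)
  }
  # crafted uniform spectrum: p flat over all 64 entries
  flat <- list(p = matrix(1 / 64, 8, 8), empty = FALSE)
  expect_equal(as.numeric(spectralEntropy(flat)), log(64), tolerance = 1e-12)
})

test_that("degenerate patches are rejected or flagged", {
  expect_error(dct2Patch(matrix(1, 2, 3)), "square")
  expect_error(dct2Patch(matrix(1, 1, 1)), "square")
  s <- spectralEntropy(dct2Patch(matrix(0, 4, 4)))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "empty"))
})

test_that("entropy map of pure noise is consistent with a Monte-Carlo oracle", {
  gen <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(64 * 64, 0, 2), 64, 64)
    m[m < 0] <- 0
    m
  }
  em <- entropyMap(gen(1), blockSize = 16L)
  vals <- entropyValues(em)
  expect_false(any(emptyMask(em)))
  # oracle: distribution of single-block entropies under the same generator
  mc <- replicate(200, {
    set.seed(sample.int(1e6, 1))
    b <- matrix(rnorm(256, 0, 2), 16, 16)
    b[b < 0] <- 0
    as.numeric(spectralEntropy(dct2Patch(b)))
  })
  expect_true(all(vals >= min(mc) - 0.2 & vals <= max(mc) + 0.2))
})

test_that("a bright disc yields near-zero entropy inside and empty blocks outside", {
  img <- matrix(0, 64, 64)
  cx <- 32.5
  for (i in 1:64) for (j in 1:64)
    if ((i - cx)^2 + (j - cx)^2 < 22.5^2) img[i, j] <- 100
  em <- entropyMap(img, blockSize = 16L)
  # block (33:48)^2 lies fully inside the disc: constant, DC only
  expect_lt(entropyValues(em)[3, 3], 1e-9)
  expect_true(emptyMask(em)[1, 1])             # corner block: all-zero
})

test_that("halving the stride refines the grid without changing coinciding blocks", {
  set.seed(3)
  img <- matrix(rexp(96 * 96), 96, 96)
  coarse <- entropyValues(entropyMap(img, blockSize = 16L))
  fine <- entropyValues(entropyMap(img, blockSize = 16L, stride = 8L))
  expect_equal(fine[seq(1, nrow(fine), 2), seq(1, ncol(fine), 2)], coarse)
})

test_that("block size larger than the image errors", {
  expect_error(entropyMap(matrix(1, 8, 8), blockSize = 16L), "exceeds")
})

test_that("projection is order-invariant along y and obeys the min property", {
  sv <- smallView()
  v <- sv$view
  # non-overlapping tiling so y-block groups can be permuted without
  # changing any block's content
  em <- entropyMap(v, blockSize = 8L, stride = 8L)
  pr <- projectView(v, em)
  st <- stackArray(v)
  groups <- split(seq_len(dim(st)[2]), (seq_len(dim(st)[2]) - 1) %/% 8)
  perm <- unlist(groups[sample(length(groups))], use.names = FALSE)
  v2 <- new("SpimView", angle = viewAngle(v), stack = st[, perm, ],
            pitch = v@pitch, provenance = "permuted")
  pr2 <- projectView(v2, entropyMap(v2, blockSize = 8L, stride = 8L))
  expect_equal(pr2@rawMip, pr@rawMip)
  expect_equal(pr2@entropy, pr@entropy)
  # min projection never exceeds any contributing per-plane block entropy
  vals <- entropyValues(em)
  vals[emptyMask(em)] <- NA
  for (bx in c(2, 5)) for (z in c(10, 40)) {
    line <- vals[bx, , z]
    if (all(is.na(line))) {
      expect_true(pr@empty[bx, z])
    } else {
      expect_equal(pr@entropy[bx, z], min(line, na.rm = TRUE))
    }
  }
  expect_error(projectView(v, NULL), "entropyMap")
})

test_that("a single emitter produces one blob and its entropy minimum there", {
  op <- smallOptics()
  ph <- smallPhantom()
  ph@emitters <- matrix(c(40, 0, 40), 1, 3)
  ph@intensity <- 5e5
  v <- acquireView(ph, op, 0, noise = FALSE)
  pr <- projectView(v, entropyMap(v, blockSize = 8L))
  expect_equal(which.max(pr@rawMip), which.max(mipAlongY <- apply(stackArray(v), c(1, 3), max)))
  blob <- arrayInd(which.max(pr@rawMip), dim(pr@rawMip))
  nonEmpty <- which(!pr@empty, arr.ind = TRUE)
  best <- nonEmpty[which.min(pr@entropy[!pr@empty]), ]
  # entropy minimum lies at the blob's block
  expect_lt(abs(best[1] - (blob[1] %/% 8 + 1)), 2)
  expect_lt(abs(best[2] - blob[2]), 9)
})
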
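# Projection registration: transform algebra, recovery of known rigid
# motions, featureless fallback, entropy-grid warping.

test_that("transform algebra: inverse and composition give identity", {
  tf <- rigidTransform2D(33, 4.5, -2.25, c(64.5, 64.5))
  id <- composeTransforms(tf, invertTransform(tf))
  expect_lt(min(id@rotation, 360 - id@rotation), 1e-6)
  expect_lt(abs(id@tx) + abs(id@tz), 1e-6)
  set.seed(1)
  pts <- matrix(runif(20, 1, 128), 10, 2)
  back <- transformPoints(invertTransform(tf), transformPoints(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("identity pair registers to the identity transform", {
  mip <- smallView()$proj@rawMip
  tf <- registerProjectionPair(mip, mip, 0)
  expect_lt(min(tf@rotation, 360 - tf@rotation), 0.2)
  expect_lt(abs(tf@tx) + abs(tf@tz), 0.2)
  expect_lt(tf@residual, 0.05)
})

test_that("a known synthetic rotation + shift is recovered on the reduced projections", {
  mip <- smallView()$proj@rawMip
  truth <- rigidTransform2D(15, 3, -2, (dim(mip) + 1) / 2)
  mov <- smartRotate:::warpImage(mip, invertTransform(truth))
  mov[is.na(mov)] <- 0
  # the 64-px projections support ~1 deg / 1 px accuracy; the full-size
  # projections are held to 0.5 deg / 0.5 px in the acceptance suite
  tf <- registerProjectionPair(mip, mov, 15)
  expect_lt(min(abs(tf@rotation - 15), 360 - abs(tf@rotation - 15)), 1)
  expect_lt(abs(tf@tx - 3), 1)
  expect_lt(abs(tf@tz + 2), 1)
  # the feature engine either agrees with the stage or is rejected; it never
  # silently returns an off-window rotation
  tfF <- tryCatch(registerProjectionPair(mip, mov, 15, engine = "feature"),
                  error = function(e) "rejected")
  okF <- identical(tfF, "rejected") || "nominal-only" %in% tfF@flags ||
    min(abs(tfF@rotation - 15), 360 - abs(tfF@rotation - 15)) <= 3.5
  expect_true(okF)
})

test_that("a pure-noise pair falls back to the nominal stage transform", {
  set.seed(2)
  a <- matrix(abs(rnorm(64 * 64)), 64, 64)
  b <- matrix(abs(rnorm(64 * 64)), 64, 64)
  tf <- registerProjectionPair(a, b, 25)
  expect_true("nominal-only" %in% tf@flags)
  expect_equal(tf@rotation, 25)
  expect_equal(c(tf@tx, tf@tz), c(0, 0))
})

test_that("the recovered rotation never strays beyond the trusted-stage window", {
  mip <- smallView()$proj@rawMip
  truth <- rigidTransform2D(10, 0, 0, (dim(mip) + 1) / 2)
  mov <- smartRotate:::warpImage(mip, invertTransform(truth))
  mov[is.na(mov)] <- 0
  # nominal deliberately 10 deg off: the constrained search cannot follow,
  # so the result is within the window of the nominal or flagged/rejected
  tf <- tryCatch(registerProjectionPair(mip, mov, 0, searchDeg = 3),
                 error = function(e) "error")
  ok <- identical(tf, "error") || "nominal-only" %in% tf@flags ||
    min(tf@rotation, 360 - tf@rotation) <= 3.5
  expect_true(ok)
})

test_that("registerViews returns identity for a single view and recovers stage angles", {
  pp <- smallPipeline()
  one <- registerViews(pp$projections[1])
  expect_length(one, 1)
  expect_equal(one[[1]]@rotation, 0)
  rots <- vapply(pp$transforms, function(t) t@rotation, numeric(1))
  err <- abs(((rots - pp$angles + 180) %% 360) - 180)
  expect_true(all(err <= 3.5))
  expect_true(median(err) < 1)
})

test_that("cyclic closure: composing successive pair transforms returns near identity", {
  pp <- smallPipeline()
  prs <- pp$projections
  n <- length(prs)
  acc <- rigidTransform2D(0, 0, 0, (dim(prs[[1]]@rawMip) + 1) / 2)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    tf <- registerProjectionPair(prs[[i]]@rawMip, prs[[j]]@rawMip,
                                 viewAngle(prs[[j]]) - viewAngle(prs[[i]]),
                                 center = acc@center)
    acc <- composeTransforms(acc, tf)
  }
  expect_lt(min(acc@rotation, 360 - acc@rotation), 1)
  expect_lt(sqrt(acc@tx^2 + acc@tz^2), 1)
})

test_that("warpEntropy: identity, lattice rotation, and round trip", {
  pr <- smallView()$proj
  id <- rigidTransform2D(0, 0, 0, (dim(pr@rawMip) + 1) / 2)
  w <- warpEntropy(pr, id)
  expect_equal(w$values, unname(pr@entropy))
  expect_equal(w$empty, unname(pr@empty))
  # synthetic square grid where a 90-degree rotation is an exact permutation
  ent <- matrix(runif(32 * 32), 32, 32)
  pr2 <- new("ViewProjection", angle = 0, rawMip = matrix(0, 32, 32),
             entropy = ent, empty = matrix(FALSE, 32, 32),
             blockSize = 1L, stride = 1L, pitch = 1)
  rot <- rigidTransform2D(90, 0, 0, c(16.5, 16.5))
  w90 <- warpEntropy(pr2, rot)
  expect_true(all(sort(w90$values) == sort(as.vector(ent))))
  back <- warpEntropy(new("ViewProjection", angle = 0, rawMip = matrix(0, 32, 32),
                          entropy = w90$values, empty = w90$empty,
                          blockSize = 1L, stride = 1L, pitch = 1),
                      invertTransform(rot))
  expect_equal(back$values, unname(ent))
  # cells warped out of the field come back flagged empty
  sh <- rigidTransform2D(0, 10, 0, c(16.5, 16.5))
  wS <- warpEntropy(pr2, sh)
  expect_true(all(wS$empty[1:10, ]))
  expect_equal(wS$values[11:32, ], unname(ent[1:22, ]))
})

test_that("the rotation-axis centre is recovered from structured projections", {
  # synthetic views rotating a blob field about a known off-centre axis
  set.seed(9)
  base <- matrix(0, 96, 96)
  for (k in 1:40) {
    i <- sample(20:76, 1); j <- sample(20:76, 1)
    base[i + (-1:1), j + (-1:1)] <- base[i + (-1:1), j + (-1:1)] + runif(1, 5, 20)
  }
  ctrTrue <- c(52, 44)
  mkProj <- function(angle) {
    img <- smartRotate:::rotateImage(base, -angle, ctrTrue)
    new("ViewProjection", angle = angle, rawMip = img,
        entropy = matrix(0, 1, 1), empty = matrix(FALSE, 1, 1),
        blockSize = 1L, stride = 1L, pitch = 1)
  }
  projs <- lapply(c(0, 40, 90, 180), mkProj)
  ctr <- estimateRotationCenter(projs, span = 12)
  expect_lt(max(abs(ctr - ctrTrue)), 3)
})
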
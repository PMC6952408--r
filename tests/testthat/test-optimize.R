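# View-set scoring and selection: additive capped coverage, exhaustive
# search against an independent enumeration oracle, greedy behaviour and
# profile updates.

# independent oracle: score a set of angles by direct evaluation of the
# capped additive model, no shared code with the package implementation
oracleScore <- function(sp, angles) {
  fits <- regionFits(sp)
  fr <- vapply(fits, function(f) {
    cmax <- f@A * exp(f@kappa) / (2 * pi * besselI(f@kappa, 0))
    tot <- sum(vapply(angles, function(x)
      f@A * exp(f@kappa * cos((x - f@mu) * pi / 180)) /
        (2 * pi * besselI(f@kappa, 0)), numeric(1)))
    if (cmax > 0) min(tot, cmax) / cmax else 1
  }, numeric(1))
  mean(fr)
}

randomProfile <- function(seed) {
  set.seed(seed)
  syntheticProfile(A = runif(36, 100, 5000), kappa = runif(36, 0.2, 6),
                   mu = runif(36, 0, 360))
}

test_that("a single view at a region's optimum covers that region fully", {
  sp <- syntheticProfile(A = 1000, kappa = 2, mu = (seq(0, 350, 10) + 5 - 135) %% 360)
  s <- scoreViewSet(sp, (5 - 135) %% 360)
  expect_equal(unname(s@perRegion[["0"]]), 1, tolerance = 1e-9)
  expect_error(scoreViewSet(sp, c(10, 10)), "distinct")
})

test_that("with kappa = 0 everywhere, all equally sized sets score identically", {
  sp <- syntheticProfile(A = 500, kappa = 0, mu = 0)
  s1 <- scoreViewSet(sp, c(0, 90, 180))
  s2 <- scoreViewSet(sp, c(15, 145, 250))
  expect_equal(meanCoverage(s1), meanCoverage(s2), tolerance = 1e-12)
})

test_that("adding an angle never decreases any region's coverage fraction", {
  for (seed in 1:10) {
    sp <- randomProfile(seed)
    set.seed(seed + 100)
    base <- sample(seq(0, 345, 15), 3)
    extra <- setdiff(seq(0, 345, 15), base)[1]
    a <- scoreViewSet(sp, base)
    b <- scoreViewSet(sp, c(base, extra))
    expect_true(all(b@perRegion >= a@perRegion - 1e-12))
  }
})

test_that("exhaustive selection agrees with the independent enumeration oracle", {
  cands <- seq(0, 330, by = 30)   # N = 12
  for (seed in 1:10) {
    sp <- randomProfile(seed)
    for (n in c(2, 3)) {
      sel <- selectViews(sp, n, cands, method = "exhaustive")
      combos <- combn(cands, n)
      best <- max(apply(combos, 2, function(s) oracleScore(sp, s)))
      expect_equal(meanCoverage(sel), best, tolerance = 1e-9)
    }
  }
})

test_that("a homogeneous profile selects an equally spaced set under the tie-break", {
  mus <- (seq(0, 350, 10) + 5 - 135) %% 360
  sp <- syntheticProfile(A = 1000, kappa = 1.5, mu = mus)
  sel <- selectViews(sp, 4, seq(0, 345, by = 15), method = "exhaustive")
  sp4 <- sort(selectedAngles(sel))
  expect_equal(diff(sp4), rep(90, 3))
  # at this kappa the capped score saturates and many sets tie the optimum;
  # greedy must reach the same score as the exhaustive optimum
  g <- selectViews(sp, 4, seq(0, 345, by = 15), method = "greedy")
  expect_equal(meanCoverage(g), meanCoverage(sel), tolerance = 1e-9)
  # with a sharper, non-saturating response greedy spreads to within one
  # candidate step of equal spacing
  sp3 <- syntheticProfile(A = 1000, kappa = 3, mu = mus)
  g3 <- selectViews(sp3, 4, seq(0, 345, by = 15), method = "greedy")
  gaps <- diff(c(sort(selectedAngles(g3)), min(selectedAngles(g3)) + 360))
  expect_lte(max(abs(gaps - 90)), 15 + 1e-9)
})

test_that("all content in one narrow sector pulls the selected angles to it", {
  # regions outside the hot sector carry no content at all (A = 0, so their
  # coverage fraction is 1 by convention and they exert no pull)
  mus <- (seq(0, 350, 10) + 5 - 135) %% 360
  A <- ifelse(seq(0, 350, 10) >= 60 & seq(0, 350, 10) < 90, 5000, 0)
  sp <- syntheticProfile(A = A, kappa = 3, mu = mus)
  sel <- selectViews(sp, 3, seq(0, 345, by = 15), method = "exhaustive")
  best <- (75 - 135) %% 360   # optimal view for the hot sector
  expect_true(any(vapply(selectedAngles(sel), function(a)
    min(abs(a - best), 360 - abs(a - best)) <= 30, logical(1))))
})

test_that("n = N returns all candidates and dominates any smaller set", {
  sp <- randomProfile(3)
  cands <- seq(0, 330, by = 30)
  all12 <- selectViews(sp, 12, cands)
  expect_setequal(selectedAngles(all12), cands)
  some <- selectViews(sp, 4, cands)
  expect_gte(meanCoverage(all12), meanCoverage(some) - 1e-12)
})

test_that("the combinatorial guard points to greedy", {
  sp <- randomProfile(1)
  expect_error(selectViews(sp, 12, seq(0, 359.9, by = 2.5)), "greedy")
})

test_that("greedy equals exhaustive for n = 1 and stays within the submodular bound", {
  gaps <- numeric(0)
  for (seed in 1:200) {
    sp <- randomProfile(seed)
    cands <- seq(0, 330, by = 30)
    g1 <- selectViews(sp, 1, cands, method = "greedy")
    e1 <- selectViews(sp, 1, cands, method = "exhaustive")
    expect_equal(meanCoverage(g1), meanCoverage(e1), tolerance = 1e-9)
    n <- sample(2:4, 1)
    g <- selectViews(sp, n, cands, method = "greedy")
    e <- selectViews(sp, n, cands, method = "exhaustive")
    expect_gte(meanCoverage(g), 0.63 * meanCoverage(e))
    gaps <- c(gaps, meanCoverage(g) / meanCoverage(e))
  }
  # report the empirical greedy gap
  cat(sprintf("\n  greedy/exhaustive ratio: min %.4f, median %.4f\n",
              min(gaps), median(gaps)))
})

test_that("selection is deterministic across repeated runs", {
  sp <- randomProfile(42)
  a <- selectViews(sp, 3, seq(0, 345, 15))
  b <- selectViews(sp, 3, seq(0, 345, 15))
  expect_identical(selectedAngles(a), selectedAngles(b))
})

test_that("updating with identical data leaves fits unchanged", {
  pp <- smallPipeline()
  sp <- pp$profile
  sub <- pp$profiles[pp$profiles$view_angle_deg %in% c(0, 90), ]
  sp2 <- updateSampleProfile(sp, sub)
  for (r in c("0", "120", "250")) {
    expect_equal(amplitude(regionFits(sp2)[[r]]), amplitude(regionFits(sp)[[r]]),
                 tolerance = 1e-6)
    expect_equal(peakAngle(regionFits(sp2)[[r]]), peakAngle(regionFits(sp)[[r]]),
                 tolerance = 1e-4)
  }
  expect_setequal(attr(sp2, "viewsReplaced"), c(0, 90))
})

test_that("an off-grid update angle is snapped with a warning", {
  pp <- smallPipeline()
  sub <- pp$profiles[pp$profiles$view_angle_deg == 15, ]
  sub$view_angle_deg <- 17
  expect_warning(sp2 <- updateSampleProfile(pp$profile, sub), "snapped")
  expect_false(17 %in% attr(sp2, "viewsReplaced"))
  expect_true(15 %in% attr(sp2, "viewsReplaced"))
})
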
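# File-level workflow: simulate/evaluate/update round trips, manifests,
# serialization, down-sampling and the command-line front end. Uses a small
# bundle (48^3 voxels at 8 um, 8 views) -- enough to exercise the plumbing.

tinyConfig <- function(seed = 21L) {
  cfg <- defaultSimConfig(seed = seed, nAngles = 8L,
                          stackDim = c(48L, 48L, 48L), pitch = 8)
  cfg
}

tinyBundle <- function() memo("tinyBundle", {
  dir <- file.path(tempdir(), "smartrotate-tiny")
  man <- simulateViews(tinyConfig(), dir)
  list(dir = dir, manifest = man)
})

tinyEval <- function() memo("tinyEval", {
  tb <- tinyBundle()
  out <- file.path(tb$dir, "report")
  res <- suppressWarnings(evaluateViews(tb$manifest, nViews = 3L, outDir = out))
  list(res = res, out = out)
})

test_that("simulate writes the full bundle and is bit-reproducible", {
  tb <- tinyBundle()
  files <- list.files(tb$dir)
  expect_true(all(c("views.json", "blank.tif", "ground_truth.csv",
                    "view_000.tif", "view_315.tif") %in% files))
  dir2 <- file.path(tempdir(), "smartrotate-tiny2")
  simulateViews(tinyConfig(), dir2)
  h1 <- tools::md5sum(file.path(tb$dir, "view_045.tif"))
  h2 <- tools::md5sum(file.path(dir2, "view_045.tif"))
  expect_equal(unname(h1), unname(h2))
  # stacks survive the float-TIFF round trip
  b <- readViewBundle(tb$manifest)
  expect_length(b$views, 8)
  expect_false(is.null(b$blank))
  cfg <- tinyConfig()
  v45 <- acquireView(smartRotate:::configPhantom(cfg),
                     smartRotate:::configOptics(cfg), 45)
  got <- b$views[[which(vapply(b$views, viewAngle, numeric(1)) == 45)]]
  expect_lt(max(abs(stackArray(got) - stackArray(v45))), 1e-4 * max(stackArray(v45)))
})

test_that("evaluate produces reports and is deterministic on identical inputs", {
  te <- tinyEval()
  expect_s4_class(te$res$profile, "SampleProfile")
  expect_s4_class(te$res$selection, "ViewSetScore")
  expect_true(all(file.exists(file.path(te$out,
    c("profile.json", "selection.json", "profiles.csv", "evaluate.log")))))
  out2 <- file.path(tinyBundle()$dir, "report2")
  res2 <- suppressWarnings(evaluateViews(tinyBundle()$manifest, nViews = 3L,
                                         outDir = out2))
  expect_identical(selectedAngles(te$res$selection), selectedAngles(res2$selection))
  expect_equal(meanCoverage(te$res$selection), meanCoverage(res2$selection))
  h1 <- tools::md5sum(file.path(te$out, "profile.json"))
  h2 <- tools::md5sum(file.path(out2, "profile.json"))
  expect_equal(unname(h1), unname(h2))
})

test_that("evaluation contracts: too few views, angular gaps, missing blank", {
  tb <- tinyBundle()
  man <- jsonlite::read_json(tb$manifest)
  # keep only 3 views
  man3 <- man; man3$views <- man$views[1:3]
  p3 <- file.path(tb$dir, "views3.json")
  jsonlite::write_json(man3, p3, auto_unbox = TRUE, digits = NA)
  expect_error(evaluateViews(p3), "at least 4")
  # a gap > 180 degrees
  mg <- man; mg$views <- man$views[c(1, 2, 3, 4)]   # 0..135: gap 225
  pg <- file.path(tb$dir, "viewsgap.json")
  jsonlite::write_json(mg, pg, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(evaluateViews(pg)), "gap")
  # auto background without a blank
  mb <- man; mb$blank <- NULL
  pb <- file.path(tb$dir, "viewsnoblank.json")
  jsonlite::write_json(mb, pb, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(evaluateViews(pb)), "blank")
})

test_that("sample profiles round-trip through JSON", {
  te <- tinyEval()
  p <- file.path(tempdir(), "prof-rt.json")
  writeSampleProfile(te$res$profile, p)
  sp2 <- readSampleProfile(p)
  f1 <- regionFits(te$res$profile); f2 <- regionFits(sp2)
  expect_equal(names(f1), names(f2))
  expect_equal(vapply(f1, amplitude, numeric(1)), vapply(f2, amplitude, numeric(1)))
  expect_equal(vapply(f1, peakAngle, numeric(1)), vapply(f2, peakAngle, numeric(1)))
  expect_equal(as.numeric(sp2@background), as.numeric(te$res$profile@background))
  expect_equal(nrow(profileTable(sp2)), nrow(profileTable(te$res$profile)))
})

test_that("update with zero new views changes nothing; real updates account their work", {
  te <- tinyEval()
  tb <- tinyBundle()
  up0 <- updateEvaluation(tb$manifest, te$res$profile, character(0), nViews = 3L)
  expect_equal(up0$viewsProcessed, 0L)
  expect_identical(selectedAngles(up0$selection), selectedAngles(te$res$selection))
  up2 <- updateEvaluation(tb$manifest, te$res$profile,
                          c("view_045.tif", "view_135.tif"), nViews = 3L)
  expect_equal(up2$viewsProcessed, 2L)
  expect_s4_class(up2$profile, "SampleProfile")
  # static sample, identical data: selection unchanged
  expect_identical(selectedAngles(up2$selection), selectedAngles(te$res$selection))
})

test_that("down-sampling strides the stack and keeps the pipeline runnable", {
  st <- array(seq_len(4 * 4 * 4), c(4, 4, 4))
  ds <- downsampleStack(st, c(2L, 2L, 1L))
  expect_equal(dim(ds), c(2L, 2L, 4L))
  expect_equal(ds[1, 1, ], st[1, 1, ])
  tb <- tinyBundle()
  res <- suppressWarnings(evaluateViews(tb$manifest, nViews = 3L,
                                        downsample = c(1L, 2L, 1L)))
  expect_s4_class(res$profile, "SampleProfile")
})

test_that("coverage curve sweeps smart and blind scores", {
  te <- tinyEval()
  cc <- coverageCurve(te$res$profile, maxViews = 5)
  expect_equal(cc$n, 1:5)
  expect_true(all(diff(cc$smart) >= -1e-9))        # more views never hurt
  expect_true(all(cc$blind_best >= cc$blind_mean - 1e-9))
  expect_true(all(cc$blind_mean >= cc$blind_worst - 1e-9))
})

test_that("the CLI dispatches simulate, evaluate, update and coverage-curve", {
  dir <- file.path(tempdir(), "cli-bundle")
  expect_invisible(runSmartRotateCli(c("-h")))
  cfgPath <- file.path(tempdir(), "cli-sim.yaml")
  yaml::write_yaml(tinyConfig(seed = 31L), cfgPath)
  out <- utils::capture.output(
    runSmartRotateCli(c("simulate", "--config", cfgPath, "--out", dir)))
  expect_true(file.exists(file.path(dir, "views.json")))
  rep <- file.path(dir, "rep")
  out <- utils::capture.output(suppressWarnings(
    runSmartRotateCli(c("evaluate", "--manifest", file.path(dir, "views.json"),
                        "--n-views", "3", "--out", rep))))
  expect_true(any(grepl("selected angles", out)))
  expect_true(file.exists(file.path(rep, "selection.json")))
  curveCsv <- file.path(dir, "curve.csv")
  out <- utils::capture.output(
    runSmartRotateCli(c("coverage-curve", "--profile",
                        file.path(rep, "profile.json"),
                        "--max-views", "4", "--out", curveCsv)))
  expect_true(file.exists(curveCsv))
  expect_equal(nrow(utils::read.csv(curveCsv)), 4)
  out <- utils::capture.output(
    runSmartRotateCli(c("update", "--manifest", file.path(dir, "views.json"),
                        "--previous", file.path(rep, "profile.json"),
                        "--new", "view_090.tif", "--n-views", "3",
                        "--out", file.path(dir, "rep2"))))
  expect_true(file.exists(file.path(dir, "rep2", "selection_trace.csv")))
  expect_equal(runSmartRotateCli("nonsense") , 1L, ignore_attr = TRUE)
})

test_that("entropy maps and transforms survive their serialization round trips", {
  pr <- smallView()
  em <- entropyMap(stackArray(pr$view), blockSize = 8L)
  base <- file.path(tempdir(), "emap-rt")
  writeEntropyMap(em, base)
  em2 <- readEntropyMap(base)
  expect_equal(blockSize(em2), blockSize(em))
  expect_equal(emptyMask(em2), emptyMask(em))
  expect_equal(entropyValues(em2), entropyValues(em), tolerance = 1e-6)
  tfs <- list("0" = rigidTransform2D(0, 0, 0, c(64.5, 64.5), residual = 0),
              "30" = rigidTransform2D(30, 1.25, -2.5, c(64.5, 64.5),
                                      residual = 0.12, flags = "nominal-only"))
  p <- file.path(tempdir(), "tfs.json")
  writeTransforms(tfs, p)
  back <- readTransforms(p)
  expect_equal(names(back), names(tfs))
  expect_equal(back[["30"]]@rotation, 30)
  expect_equal(back[["30"]]@tx, 1.25)
  expect_equal(back[["30"]]@flags, "nominal-only")
})
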
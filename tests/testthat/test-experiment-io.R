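test_that("image IO round-trips values and pixel size", {
  tmp <- withr::local_tempdir()
  set.seed(61)
  x <- matrix(runif(256), 16, 16)
  nii <- file.path(tmp, "img.nii.gz")
  saveImage(x, nii, pixelSizeMm = 4.07)
  back <- loadImage(nii)
  expect_equal(back$values, x, tolerance = 1e-6)
  expect_lt(abs(back$pixelSizeMm - 4.07), 1e-6)
  csv <- file.path(tmp, "img.csv")
  saveImage(x, csv)
  expect_equal(loadImage(csv, pixelSizeMm = 2)$values, x,
               ignore_attr = TRUE)
  # 3D volumes require a slice index
  arr <- array(runif(4^3), c(4, 4, 4))
  vol <- file.path(tmp, "vol.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), vol)
  expect_error(loadImage(vol), "slice")
  expect_equal(loadImage(vol, slice = 2)$values, arr[, , 2],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("dataset directories round-trip through the JSON manifest", {
  tmp <- withr::local_tempdir()
  sys <- smallSystem()
  d <- simulateSlices(3, smallTumorConfig(), smallBackgroundParams(), sys,
                      seed = 62)
  writeDataset(d, file.path(tmp, "ds"))
  back <- readDataset(file.path(tmp, "ds"))
  expect_equal(length(back$images), 3)
  expect_equal(values(back$images[[2]]), values(d$images[[2]]),
               tolerance = 1e-6)
  expect_equal(values(back$tfa[[3]]), values(d$tfa[[3]]), tolerance = 1e-6)
  expect_equal(back$areasCm2, d$areasCm2, tolerance = 1e-6)
})

test_that("estimator checkpoints reload to identical predictions", {
  tmp <- withr::local_tempdir()
  cfg <- networkConfig(16, depth = 2, baseChannels = 3)
  set.seed(63)
  est <- buildEstimator(cfg)
  path <- file.path(tmp, "ckpt.json")
  saveEstimator(est, path)
  back <- loadEstimator(path)
  x <- matrix(runif(256), 16, 16)
  expect_equal(values(predictTFA(back, x)), values(predictTFA(est, x)),
               tolerance = 1e-12)
})

test_that("experiment configurations round-trip through JSON", {
  tmp <- withr::local_tempdir()
  cfg <- experimentConfig(imageDim = 32L, gridRatio = 4L, seed = 9L)
  p <- file.path(tmp, "cfg.json")
  saveConfig(cfg, p)
  expect_identical(loadConfig(p), cfg)
})

test_that("a small end-to-end experiment is reproducible and complete", {
  sys <- smallSystem()
  net <- networkConfig(32, depth = 2, baseChannels = 4)
  tc <- trainingConfig(epochs = 4, batchSize = 6)
  run1 <- runExperiment(12, 4, smallTumorConfig(), smallBackgroundParams(),
                        sys, net, tc, seed = 64)
  rep1 <- run1$report
  expect_s4_class(rep1, "EvalReport")
  expect_true(is.finite(rep1@pixelwiseEmse))
  expect_true(is.finite(rep1@normalizedAreaEmse))
  expect_true(all(is.finite(rep1@dscMeanCi)))
  expect_true(all(is.finite(rep1@jscMeanCi)))
  expect_identical(dim(rep1@biasMap), c(32L, 32L))
  expect_gt(nrow(rep1@perBin), 0)
  # training and test tumors are disjoint draws
  expect_false(any(run1$train$areasCm2 %in% run1$test$areasCm2))
  # identical config + seed => byte-identical report JSON
  tmp <- withr::local_tempdir()
  run2 <- runExperiment(12, 4, smallTumorConfig(), smallBackgroundParams(),
                        sys, net, tc, seed = 64)
  f1 <- file.path(tmp, "r1.json"); f2 <- file.path(tmp, "r2.json")
  writeReport(run1$report, f1); writeReport(run2$report, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(runExperiment(12, 0, smallTumorConfig(),
                             smallBackgroundParams(), sys, net, tc),
               ">= 1")
})
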
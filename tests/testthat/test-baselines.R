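test_that("SUV-max thresholding selects the expected pixels", {
  img <- matrix(1, 16, 16)
  roi <- roiBox(c(4, 10), c(4, 10), 16)
  # constant ROI: every pixel equals the max
  out <- suvmaxThreshold(img, roi)
  expect_true(all(out[roi$rows, roi$cols] == 1))
  expect_equal(sum(out), 49)
  # single hot pixel: background at 1 < 0.4 * 10
  img[6, 6] <- 10
  out <- suvmaxThreshold(img, roi, 0.40)
  expect_equal(which(out == 1), which(matrix(seq_len(256), 16, 16) == 86))
  # output is always confined to the ROI
  expect_true(all(out[-(4:10), ] == 0))
  expect_error(roiBox(c(5, 2), c(1, 3), 16), "ROI")
  expect_error(suvmaxThreshold(img, roi, 1.2), "fraction")
})

test_that("thresholded area shrinks as the threshold fraction grows", {
  sys <- smallSystem()
  blurred <- tfaseg:::gaussianBlur(diskMatrix(32, 5), 2)
  roi <- roiBox(c(8, 25), c(8, 25), 32)
  areas <- vapply(c(0.3, 0.4, 0.5),
                  function(f) sum(suvmaxThreshold(blurred, roi, f)),
                  numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("the PVE boxcar filter is an identity at width 1 and conserves mass", {
  set.seed(51)
  m <- tfaMap(matrix(runif(256), 16, 16), 1)
  expect_equal(values(pveAffectedMask(m, 1)), values(m))
  expect_error(pveAffectedMask(m, 4), "odd")
  # single interior unit pixel spreads to a 3x3 block of 1/9
  pt <- matrix(0, 9, 9); pt[5, 5] <- 1
  sm <- values(pveAffectedMask(tfaMap(pt, 1), 3))
  expect_equal(sm[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_true(all(sm[-(4:6), ] == 0))
  # interior tumors: total area preserved
  inner <- matrix(0, 16, 16); inner[6:10, 7:11] <- 1
  expect_lt(abs(sum(values(pveAffectedMask(tfaMap(inner, 1), 5))) -
                sum(inner)), 1e-9)
})

test_that("PVE-affected binary masks overestimate small tumors most", {
  set.seed(52)
  ratioFor <- function(areaRange) replicate(15, {
    cfg <- tumorConfig(areaRangeCm2 = areaRange, gridRatio = 4L)
    s <- sampleTumorSupport(cfg, 32, 4.07)
    map <- computeTFA(s, 4, 0.1656)
    tumorArea(pveBinaryMask(map, 3)) / tumorArea(map)
  })
  small <- ratioFor(c(1, 2)); large <- ratioFor(c(6, 9))
  expect_gt(mean(small), 1)          # spill-out dominates small tumors
  expect_gt(mean(small), mean(large))
})

test_that("area ratio study reports exact ratios and respects binning", {
  set.seed(53)
  truths <- lapply(1:12, function(i)
    computeTFA(sampleTumorSupport(smallTumorConfig(), 32, 4.07), 4, 0.1656))
  ident <- areaRatioStudy(truths, truths)
  expect_true(all(abs(ident$ratioMean - 1) < 1e-12))
  expect_true(all(ident$dscMean == 1))
  expect_equal(sum(ident$n), 12)
  scaled <- lapply(truths, function(m) tfaMap(values(m) * 0.5,
                                              m@pixelAreaCm2))
  rs <- areaRatioStudy(truths, scaled)
  expect_true(all(abs(rs$ratioMean - 0.5) < 1e-12))
})

test_that("the classification baseline trains on binarized targets", {
  set.seed(54)
  truths <- lapply(1:12, function(i) {
    m <- matrix(0, 16, 16)
    m[6:10, 6:10] <- runif(25, 0.6, 1)
    tfaMap(m, 1)
  })
  images <- lapply(truths, function(m)
    values(m) + matrix(abs(rnorm(256, 0.2, 0.05)), 16, 16))
  cfg <- networkConfig(16, depth = 2, baseChannels = 3)
  tc <- trainingConfig(epochs = 4, batchSize = 4, seed = 3)
  clf <- classificationBaselineTrain(images, truths, cfg, tc)
  expect_identical(clf@meta$kind, "classification")
  out <- values(predictTFA(clf, images[[1]], 1))
  expect_true(all(out > 0 & out < 1))
  clf2 <- classificationBaselineTrain(images, truths, cfg, tc)
  expect_identical(clf@weights, clf2@weights)
})
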
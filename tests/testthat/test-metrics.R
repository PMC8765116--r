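test_that("estimation metrics match their definitions on hand examples", {
  a <- tfaMap(matrix(c(1, 0), 1, 2), 1)
  ah <- tfaMap(matrix(c(0.5, 0.5), 1, 2), 1)
  expect_equal(pixelwiseEMSE(list(a), list(ah)), 0.5)
  expect_equal(pixelwiseEMSE(list(a), list(a)), 0)
  b <- tfaMap(matrix(0.5, 2, 2), 1)
  bh <- tfaMap(matrix(0.55, 2, 2), 1)   # areas 2 and 2.2
  expect_equal(normalizedAreaEMSE(list(b), list(bh)), 0.01)
  expect_equal(normalizedAreaEMSE(list(b), list(b)), 0)
  # pixel area cancels in the normalized ratio
  b2 <- tfaMap(matrix(0.5, 2, 2), 7); bh2 <- tfaMap(matrix(0.55, 2, 2), 7)
  expect_equal(normalizedAreaEMSE(list(b2), list(bh2)), 0.01)
  expect_error(normalizedAreaEMSE(list(tfaMap(matrix(0, 2, 2), 1)), list(b)),
               "positive")
  expect_error(pixelwiseEMSE(list(), list()), "nonempty")
})

test_that("estimation metrics equal brute-force accumulation on random pairs", {
  set.seed(31)
  truths <- lapply(1:100, function(i) matrix(runif(64), 8, 8))
  ests <- lapply(1:100, function(i) matrix(runif(64), 8, 8))
  acc <- 0
  for (i in 1:100) {
    s <- 0
    for (m in 1:64) s <- s + (ests[[i]][m] - truths[[i]][m])^2
    acc <- acc + s
  }
  expect_equal(pixelwiseEMSE(truths, ests), acc / 100)
  biasOracle <- matrix(0, 8, 8)
  for (i in 1:100) biasOracle <- biasOracle + (ests[[i]] - truths[[i]]) / 100
  expect_equal(ensembleBias(truths, ests, P = 20, N = 5), biasOracle)
  expect_error(ensembleBias(truths, ests, P = 7, N = 7), "P \\* N")
})

test_that("ensemble bias reproduces constant offsets", {
  truths <- lapply(1:4, function(i) matrix(0.3, 3, 3))
  ests <- lapply(1:4, function(i) matrix(0.4, 3, 3))
  expect_equal(ensembleBias(truths, ests), matrix(0.1, 3, 3))
  expect_equal(ensembleBias(truths, truths), matrix(0, 3, 3))
})

test_that("fuzzy confusion satisfies the exact cardinality identities", {
  set.seed(32)
  for (rep in 1:25) {
    a <- matrix(runif(100), 10, 10)
    ah <- matrix(runif(100), 10, 10)
    cf <- fuzzyConfusion(a, ah)
    expect_equal(cf@tp + cf@fp + cf@tn + cf@fn, 100)
    expect_equal(cf@tp + cf@fn, sum(a))
    expect_equal(cf@tp + cf@fp, sum(ah))
    # swapping the maps swaps FP and FN and preserves TP
    sw <- fuzzyConfusion(ah, a)
    expect_equal(sw@tp, cf@tp)
    expect_equal(sw@fp, cf@fn)
    expect_equal(sw@fn, cf@fp)
  }
})

test_that("fuzzy confusion matches the hand example and binary counting", {
  cf <- fuzzyConfusion(matrix(c(1, 0.5, 0), 1, 3),
                       matrix(c(0.5, 0.5, 0.5), 1, 3))
  expect_equal(cf@tp, 1.0); expect_equal(cf@fp, 0.5)
  expect_equal(cf@fn, 0.5); expect_equal(cf@tn, 1.0)
  ov <- dscJsc(cf)
  expect_equal(unname(ov["dsc"]), 2 / 3)
  expect_equal(unname(ov["jsc"]), 1 / 2)
  # on binary masks the fuzzy cardinalities are the classical set counts
  set.seed(33)
  for (rep in 1:100) {
    a <- matrix(as.numeric(runif(64) < 0.5), 8, 8)
    b <- matrix(as.numeric(runif(64) < 0.5), 8, 8)
    cf <- fuzzyConfusion(a, b)
    expect_equal(cf@tp, sum(a == 1 & b == 1))
    expect_equal(cf@fp, sum(a == 0 & b == 1))
    expect_equal(cf@fn, sum(a == 1 & b == 0))
    expect_equal(cf@tn, sum(a == 0 & b == 0))
  }
  expect_error(fuzzyConfusion(matrix(2, 1, 1), matrix(0.5, 1, 1)), "0, 1")
})

test_that("DSC and JSC are tied by JSC = DSC / (2 - DSC)", {
  set.seed(34)
  for (rep in 1:50) {
    cf <- fuzzyConfusion(matrix(runif(49), 7, 7), matrix(runif(49), 7, 7))
    ov <- dscJsc(cf)
    expect_equal(unname(ov["jsc"]), unname(ov["dsc"] / (2 - ov["dsc"])))
    expect_true(all(ov >= 0 & ov <= 1))
  }
  # identical, disjoint, and doubly-empty maps
  a <- diskMatrix(10, 3)
  expect_equal(unname(dscJsc(fuzzyConfusion(a, a))), c(1, 1))
  b <- matrix(0, 10, 10); b[1, 1] <- 1
  a2 <- matrix(0, 10, 10); a2[10, 10] <- 1
  expect_equal(unname(dscJsc(fuzzyConfusion(a2, b))), c(0, 0))
  z <- matrix(0, 5, 5)
  expect_equal(unname(dscJsc(fuzzyConfusion(z, z))), c(1, 1))
})

test_that("summaries and paired tests behave as stated", {
  s <- summarizeMetric(rep(0.8, 5))
  expect_equal(unname(s), c(0.8, 0.8, 0.8))
  # hand-computed t interval for a known 5-value sample
  x <- c(1, 2, 3, 4, 5)
  half <- qt(0.975, 4) * sd(x) / sqrt(5)
  expect_equal(unname(summarizeMetric(x)), c(3, 3 - half, 3 + half))
  expect_error(summarizeMetric(1), "two")
  expect_equal(pairedTest(x, x), 1)
  expect_equal(pairedTest(x, x + 1), 0)
  set.seed(35)
  y <- x + rnorm(5, 0, 0.5)
  expect_equal(pairedTest(x, y), t.test(x, y, paired = TRUE)$p.value)
})

test_that("isocontours nest by level and handle degenerate maps", {
  flat <- tfaMap(matrix(0.5, 8, 8), 1)
  ct <- isocontours(flat)
  expect_length(ct[["0.3333"]], 0)   # no crossing on a constant map
  expect_length(ct[["0.6667"]], 0)
  # disk-support TFA map: higher levels enclose less area
  set.seed(36)
  disk <- diskMatrix(64, 20)
  map <- computeTFA(disk, 4, 1)
  ct <- isocontours(map)
  areas <- vapply(ct, tfaseg:::isocontourArea, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(isocontours(map, levels = c(-0.2)), "levels")
})

test_that("isocontour nesting holds across random simulated tumors", {
  set.seed(37)
  cfg <- smallTumorConfig()
  for (rep in 1:50) {
    s <- sampleTumorSupport(cfg, 32, 4.07)
    map <- computeTFA(s, 4, 1)
    areas <- vapply(isocontours(map), tfaseg:::isocontourArea, numeric(1))
    expect_true(all(diff(areas) <= 1e-9))
  }
})
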
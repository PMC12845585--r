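test_that("confusion updates match hand counts and a loop oracle", {
  cm <- pixelConfusion(2L)
  ## perfect all-ones prediction on 2x2
  cm1 <- confusionUpdate(cm, matrix(1L, 2, 2), matrix(1L, 2, 2))
  cc <- confusionCounts(cm1)
  expect_equal(cc$tp, c(0, 4))
  expect_equal(cc$fp + cc$fn, c(0, 0))
  ## pred all 0, gt all 1: 4 false negatives for class 1, 4 FP for class 0
  cm2 <- confusionUpdate(cm, matrix(0L, 2, 2), matrix(1L, 2, 2))
  cc2 <- confusionCounts(cm2)
  expect_equal(cc2$fn[2], 4)
  expect_equal(cc2$fp[1], 4)
  ## random masks vs naive loop, accumulated in two chunks
  set.seed(51)
  pred <- matrix(sample(0:1, 64, TRUE), 8)
  gt <- matrix(sample(0:1, 64, TRUE), 8)
  cm3 <- confusionUpdate(pixelConfusion(2L), pred, gt)
  expect_equal(cm3@counts, confusionLoopOracle(pred, gt, 2))
  ## streaming equals single-shot
  cmA <- confusionUpdate(confusionUpdate(pixelConfusion(2L),
                                         pred[1:4, ], gt[1:4, ]),
                         pred[5:8, ], gt[5:8, ])
  expect_equal(cmA@counts, cm3@counts)
  expect_error(confusionUpdate(cm, matrix(2L, 2, 2), matrix(0L, 2, 2)),
               "labels")
})

test_that("metrics reproduce the worked 2x2 example", {
  ## gt [[1,1],[0,0]], pred [[1,0],[0,0]] (row-wise notation)
  gt <- rbind(c(1L, 1L), c(0L, 0L))
  pred <- rbind(c(1L, 0L), c(0L, 0L))
  m <- computeMetrics(confusionUpdate(pixelConfusion(2L), pred, gt))
  expect_equal(m$mIoU, 7 / 12, tolerance = 1e-12)
  expect_equal(m$mPA, 0.75, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.75, tolerance = 1e-12)
  expect_equal(m$mF1, 11 / 15, tolerance = 1e-12)
})

test_that("metrics agree with the formula oracle on random mask pairs", {
  set.seed(52)
  for (rep in 1:25) {
    pred <- matrix(sample(0:1, 36, TRUE), 6)
    gt <- matrix(sample(0:1, 36, TRUE), 6)
    cm <- confusionUpdate(pixelConfusion(2L), pred, gt)
    m <- computeMetrics(cm)
    o <- metricFormulaOracle(cm@counts)
    expect_equal(m$mIoU, o$mIoU, tolerance = 1e-12)
    expect_equal(m$mPA, o$mPA, tolerance = 1e-12)
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(m$mF1, o$mF1, tolerance = 1e-12)
  }
})

test_that("perfect prediction yields all metrics 1; empty accumulator errors", {
  set.seed(53)
  gt <- matrix(sample(0:1, 25, TRUE), 5)
  m <- computeMetrics(confusionUpdate(pixelConfusion(2L), gt, gt))
  expect_equal(unlist(m[c("mIoU", "mPA", "accuracy", "mF1")]),
               c(mIoU = 1, mPA = 1, accuracy = 1, mF1 = 1))
  expect_error(computeMetrics(pixelConfusion(2L)), "no pixels")
})

test_that("metrics are invariant under consistent relabeling", {
  set.seed(54)
  pred <- matrix(sample(0:1, 49, TRUE), 7)
  gt <- matrix(sample(0:1, 49, TRUE), 7)
  m1 <- computeMetrics(confusionUpdate(pixelConfusion(2L), pred, gt))
  m2 <- computeMetrics(confusionUpdate(pixelConfusion(2L), 1L - pred,
                                       1L - gt))
  expect_equal(m1[c("mIoU", "mPA", "accuracy", "mF1")],
               m2[c("mIoU", "mPA", "accuracy", "mF1")])
})

test_that("pooled accuracy equals trace over total for two classes", {
  set.seed(55)
  pred <- matrix(sample(0:1, 100, TRUE), 10)
  gt <- matrix(sample(0:1, 100, TRUE), 10)
  cm <- confusionUpdate(pixelConfusion(2L), pred, gt)
  m <- computeMetrics(cm)
  expect_equal(m$accuracy, sum(diag(cm@counts)) / sum(cm@counts))
  ## the literal per-class 4-way decomposition sums to N * total, so the
  ## pooled form used here equals sum(TP) / total
  cc <- confusionCounts(cm)
  expect_equal(sum(cc$tp + cc$tn + cc$fp + cc$fn), 2 * sum(cm@counts))
  expect_equal(sum(cc$tp) / sum(cm@counts), m$accuracy)
})

test_that("absent classes follow the pinned zero-division rule", {
  pred <- matrix(0L, 3, 3)
  gt <- matrix(0L, 3, 3)
  cm <- confusionUpdate(pixelConfusion(2L), pred, gt)
  expect_equal(computeMetrics(cm, absent = "perfect")$mIoU, 1)
  expect_equal(computeMetrics(cm, absent = "skip")$mIoU, 1)
  expect_equal(computeMetrics(cm, absent = "skip")$iou, c(1, 1))
})

test_that("FPS benchmark definition and constraints", {
  m <- buildModel(feswConfig(downsample = "maxpool", simam = FALSE,
                             ema = FALSE, feamCount = 0L), seed = 1)
  fps <- benchmarkFps(m, nImages = 1L, resolution = 32L, warmup = 1L)
  expect_gt(fps, 0)
  ## n = 1: FPS is the reciprocal of the measured single-image time
  expect_equal(as.numeric(fps), 1 / attr(fps, "secondsPerImage"),
               tolerance = 1e-9)
  expect_error(benchmarkFps(m, nImages = 1L, resolution = 479L), "divisible")
})
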
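test_that("hybrid loss and its gradient agree with finite differences", {
  set.seed(81)
  logits <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  masks <- array(sample(0:1, 72, TRUE), c(6, 6, 2))
  ls <- hybridLoss(logits, masks)
  expect_true(is.finite(ls$loss) && ls$loss > 0)
  for (i in sample(length(logits), 8)) {
    e <- 1e-5
    lp <- logits; lp[i] <- lp[i] + e
    lm <- logits; lm[i] <- lm[i] - e
    num <- (hybridLoss(lp, masks)$loss - hybridLoss(lm, masks)$loss) /
      (2 * e)
    expect_equal(ls$dlogits[i], num, tolerance = 1e-5)
  }
})

test_that("two identically-seeded runs produce identical losses", {
  scenes <- synthDataset(4, baseSeed = 20, size = 32)
  cfg <- feswConfig(downsample = "maxpool", simam = FALSE, ema = FALSE,
                    feamCount = 0L)
  tc <- trainConfig(batchSize = 2L, epochs = 1L, lr = 1e-3, steps = 2L,
                    seed = 11, logEvery = 1L)
  f1 <- trainModel(buildModel(cfg, seed = 4), scenes, tc)
  f2 <- trainModel(buildModel(cfg, seed = 4), scenes, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_equal(f1$model@params, f2$model@params)
})

test_that("a couple of optimisation steps reduce the training loss", {
  set.seed(82)
  scenes <- synthDataset(4, baseSeed = 30, size = 32)
  cfg <- feswConfig(feamScales = smallFeamScales)
  tc <- trainConfig(batchSize = 4L, epochs = 8L, lr = 2e-3, steps = 8L,
                    seed = 12, logEvery = 1L, evalEvery = 8L)
  fit <- trainModel(buildModel(cfg, seed = 8), scenes, tc)
  h <- fit$history
  ## single Adam steps can wobble; the optimisation must still descend
  expect_lt(min(h$loss[-1]), h$loss[1])
})

test_that("evaluation is self-consistent and streaming-invariant", {
  scenes <- synthDataset(6, baseSeed = 40, size = 32)
  cfg <- feswConfig(downsample = "maxpool", simam = FALSE, ema = FALSE,
                    feamCount = 0L)
  m <- buildModel(cfg, seed = 9)
  ## evaluating a model against its own hard predictions is perfect
  preds <- lapply(scenes, function(s) {
    lg <- predictLogits(m, s$image)
    list(image = s$image,
         mask = argmaxClasses(asBatchLocal(lg))[, , 1])
  })
  m1 <- evaluateModel(m, preds, batchSize = 2L)
  expect_equal(m1$mIoU, 1)
  expect_equal(m1$accuracy, 1)
  ## identical reports on repeated evaluation
  e1 <- evaluateModel(m, scenes, batchSize = 2L)
  e2 <- evaluateModel(m, scenes, batchSize = 2L)
  expect_identical(e1, e2)
  ## streamed batches equal a manual single-shot confusion computation
  cm <- pixelConfusion(2L)
  for (s in scenes) {
    lg <- predictLogits(m, s$image)
    cm <- confusionUpdate(cm, argmaxClasses(asBatchLocal(lg))[, , 1],
                          s$mask)
  }
  expect_equal(e1[c("mIoU", "mPA", "accuracy", "mF1")],
               computeMetrics(cm)[c("mIoU", "mPA", "accuracy", "mF1")])
})

test_that("every ablation variant trains for two steps without error", {
  scenes <- synthDataset(2, baseSeed = 50, size = 32)
  tc <- trainConfig(batchSize = 2L, epochs = 1L, lr = 1e-3, steps = 2L,
                    seed = 13, logEvery = 10L)
  for (nm in names(ablationConfigs())) {
    cfg <- ablationConfigs()[[nm]]
    cfg@feamScales <- smallFeamScales
    fit <- trainModel(buildModel(cfg, seed = 14), scenes, tc)
    expect_true(all(is.finite(unlist(fit$model@params))), label = nm)
    rm(fit)
    gc(FALSE)
  }
})
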
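test_that("configuration validity is enforced", {
  expect_error(feswConfig(widths = c(64L, 128L, 256L, 512L, 1000L)),
               "double")
  expect_error(feswConfig(downsample = "stride"), "maxpool")
  expect_error(feswConfig(ema = TRUE, emaGroups = 7L), "divisible")
  expect_error(feswConfig(feamCount = 5L), "feamScales|between")
  expect_error(feswConfig(simamLambda = 0), "positive")
})

test_that("baseline forward satisfies the shape contract", {
  cfg <- feswConfig(downsample = "maxpool", simam = FALSE, ema = FALSE,
                    feamCount = 0L)
  m <- buildModel(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- predictLogits(m, x)
  expect_equal(dim(y), c(64L, 64L, 2L, 2L))
  expect_true(all(is.finite(y)))
})

test_that("parameter counts: baseline, zero-cost SimAM, exact block deltas", {
  cfgs <- ablationConfigs()
  n <- vapply(cfgs, function(cf) {
    k <- nParameters(buildModel(cf))
    gc(FALSE)
    k
  }, 1)
  ## baseline near the canonical 31.031 M U-Net figure
  expect_equal(n[["unet"]], 31037698)
  expect_lt(abs(n[["unet"]] / 1e6 - 31.031) / 31.031, 0.003)
  ## SimAM adds exactly zero parameters
  expect_equal(n[["+simam"]], n[["unet"]])
  expect_equal(n[["fesw"]],
               nParameters(buildModel(feswConfig(simam = FALSE))),
               ignore_attr = TRUE)
  ## exact module increments
  expect_equal(n[["+ema"]] - n[["unet"]], 164352)
  expect_equal(n[["+hwd"]] - n[["unet"]], 1395520)
  ## additivity of the enabled blocks
  expect_equal(n[["+ema+simam+hwd"]], n[["unet"]] + 164352 + 1395520)
  expect_equal(n[["fesw"]], n[["+ema+hwd+feam"]])
  ## monotonicity: every added block except SimAM strictly increases size
  expect_true(all(n[c("+ema", "+hwd", "+feam")] > n[["unet"]]))
  rep <- countParameters(buildModel(cfgs$fesw))
  expect_equal(sum(rep$breakdown$parameters), rep$total)
  expect_equal(rep$millions, round(rep$total / 1e6, 3))
  expect_output(print(rep), "Learnable parameters")
})

test_that("every ablation variant builds and runs a small forward pass", {
  set.seed(71)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  for (nm in names(ablationConfigs())) {
    cfg <- ablationConfigs()[[nm]]
    cfg@feamScales <- smallFeamScales # fit the 32x32 test resolution
    m <- buildModel(cfg, seed = 2)
    y <- predictLogits(m, x)
    expect_equal(dim(y), c(32L, 32L, 2L, 1L))
    expect_true(all(is.finite(y)), label = nm)
  }
})

test_that("FEAM-count variants grow strictly in parameters", {
  n <- vapply(1:4, function(k)
    nParameters(buildModel(feswConfig(feamCount = k))), 1)
  expect_true(all(diff(n) > 0))
})

test_that("eval-mode forward is bitwise deterministic; zeros stay finite", {
  cfg <- feswConfig(feamScales = smallFeamScales)
  m <- buildModel(cfg, seed = 5)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(predictLogits(m, x), predictLogits(m, x))
  y0 <- predictLogits(m, array(0, c(32, 32, 3, 1)))
  expect_true(all(is.finite(y0)))
  expect_error(predictLogits(m, array(0, c(30, 32, 3, 1))),
               "divisible by 16")
})

test_that("full-model gradient w.r.t. FEAM alpha passes finite differences", {
  set.seed(72)
  cfg <- feswConfig(feamScales = smallFeamScales)
  m <- buildModel(cfg, seed = 6)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  fw <- feswForward(m@config, m@params, m@buffers, x, training = TRUE,
                    keepCache = TRUE)
  dl <- array(rnorm(length(fw$logits)), dim(fw$logits))
  g <- feswBackward(m@config, m@params, fw$cache, dl)
  loss <- function(p) {
    ff <- feswForward(m@config, p, m@buffers, x, training = TRUE,
                      keepCache = FALSE)
    sum(ff$logits * dl)
  }
  nm <- "feam1.alpha1"
  expect_true(any(g[[nm]] != 0))
  ok <- 0
  idx <- sample(length(m@params[[nm]]), 4)
  for (i in idx) {
    e <- 5e-2
    pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + e
    pm <- m@params; pm[[nm]][i] <- pm[[nm]][i] - e
    num <- (loss(pp) - loss(pm)) / (2 * e)
    if (abs(g[[nm]][i] - num) <= 0.1 * max(abs(num), 1e-2)) ok <- ok + 1
  }
  ## single-precision convolutions put a noise floor under the quotient;
  ## most probes must agree within 10%
  expect_gte(ok, 3)
})

test_that("checkpoints round-trip the configuration and weights", {
  cfg <- feswConfig(feamScales = smallFeamScales, feamInit = "random")
  m <- buildModel(cfg, seed = 3)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_equal(feswunet:::configAsList(modelConfig(m2)),
               feswunet:::configAsList(cfg))
  expect_equal(m2@params, m@params)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(predictLogits(m, x), predictLogits(m2, x))
  file.remove(path)
})
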
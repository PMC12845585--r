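test_that("weight projection: identity, constants, and the bilinear oracle", {
  set.seed(41)
  g <- matrix(rnorm(900), 30, 30)
  expect_identical(feamProjectWeights(g, 30, 30), g)
  expect_equal(feamProjectWeights(matrix(4.2, 5, 5), 12, 7),
               matrix(4.2, 12, 7), tolerance = 1e-12)
  g2 <- matrix(c(0, 0, 1, 1), 2, 2) # [[0,1],[0,1]]
  pr <- feamProjectWeights(g2, 2, 4)
  for (i in 1:2) for (j in 1:4)
    expect_equal(pr[i, j], bilinearPointOracle(g2, i, j, 2, 4))
  expect_equal(pr[1, ], c(0, 1 / 3, 2 / 3, 1))
})

test_that("frequency modulation: identity, scaling and DC projection", {
  set.seed(42)
  x <- randomFeature(8, 6, 3, 2)
  one <- matrix(1, 8, 6)
  zero <- matrix(0, 8, 6)
  expect_lt(max(abs(freqModulate(x, one, zero) - x)), 1e-5)
  expect_lt(max(abs(freqModulate(x, 2 * one, zero) - 2 * x)), 1e-5)
  ## alpha = 1 only at the zero-frequency bin: per-channel spatial mean
  dc <- zero
  dc[1, 1] <- 1
  y <- freqModulate(x, dc, zero)
  for (n in 1:2) for (ch in 1:3)
    expect_equal(as.vector(y[, , ch, n]),
                 rep(mean(x[, , ch, n]), 48), tolerance = 1e-10)
  expect_error(freqModulate(x, matrix(1, 4, 4), matrix(0, 4, 4)), "match")
})

test_that("unitary masking never increases energy (Parseval)", {
  set.seed(43)
  x <- randomFeature(8, 8, 2)
  mask <- matrix(rbinom(64, 1, 0.5), 8, 8)
  y <- freqModulate(x, mask, matrix(0, 8, 8))
  for (ch in 1:2)
    expect_lte(sum(y[, , ch, 1]^2), sum(x[, , ch, 1]^2) + 1e-8)
})

test_that("spatial gate scales pixels consistently across channels", {
  set.seed(44)
  x <- randomFeature(5, 4, 3)
  a <- matrix(runif(20), 5, 4)
  expect_equal(spatialGate(x, matrix(1, 5, 4)), x)
  expect_equal(spatialGate(x, matrix(0, 5, 4)), x * 0)
  y <- spatialGate(x, a)
  for (ch in 1:3) for (i in 1:5) for (j in 1:4)
    expect_equal(y[i, j, ch, 1], a[i, j] * x[i, j, ch, 1])
})

test_that("scale fusion averages branch sums", {
  set.seed(45)
  x <- randomFeature(4, 4, 2)
  idBranch <- list(freq = x, sp = x)
  expect_equal(fuseScales(list(idBranch, idBranch)), 2 * x)
  z <- list(freq = x * 0, sp = x * 0)
  expect_equal(fuseScales(list(z, z, z)), x * 0)
  a <- list(freq = randomFeature(4, 4, 2), sp = randomFeature(4, 4, 2))
  expect_equal(fuseScales(list(a)), a$freq + a$sp)
  expect_error(fuseScales(list()), "non-empty")
})

test_that("channel gate matches a naive recomputation and bounds output", {
  set.seed(46)
  C <- 8
  r <- 4
  p <- feamInit(c(2L, 4L), C, reduction = r, init = "random")$gate
  y <- randomFeature(5, 5, C, 2)
  out <- channelGate(y, p)
  ## naive recomputation per sample
  for (n in 1:2) {
    avg <- vapply(1:C, function(ch) mean(y[, , ch, n]), 1)
    mx <- vapply(1:C, function(ch) max(y[, , ch, n]), 1)
    mlp <- function(d) p$W2 %*% pmax(p$W1 %*% d + p$b1, 0)
    g <- 1 / (1 + exp(-(mlp(avg) + mlp(mx) + p$b2)))
    expect_equal(as.vector(out$gate[, n]), as.vector(g), tolerance = 1e-10)
  }
  expect_true(all(out$gate > 0 & out$gate < 1))
  expect_true(all(abs(out$y) <= abs(y)))
  expect_equal(channelGate(y * 0, p)$y, y * 0)
  expect_error(channelGate(randomFeature(3, 3, 2), p), "match")
})

test_that("identity-initialised FEAM gives pre-gate output exactly 2X", {
  set.seed(47)
  for (scales in list(c(2L, 4L), c(3L, 6L), 5L)) {
    p <- feamInit(scales, 8L, init = "identity")
    x <- randomFeature(8, 8, 8, 2)
    out <- feamApply(x, p)
    expect_lt(max(abs(out$fused - 2 * x)), 1e-5)
  }
})

test_that("FEAM rejects scales larger than the hosting feature map", {
  p <- feamInit(c(8L, 16L), 8L)
  expect_error(feamApply(randomFeature(8, 8, 8), p), "exceed")
})

test_that("gradients flow to the spectral weights (finite differences)", {
  set.seed(48)
  p <- feamInit(c(2L, 4L), 4L, init = "identity")
  x <- randomFeature(4, 4, 4, 1)
  fw <- feamApply(x, p, keepCache = TRUE)
  r <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- feamBackward(p, fw$cache, r)
  f <- function(pp) sum(feamApply(x, pp)$y * r)
  for (s in 1:2) for (part in c("alpha", "beta")) {
    v <- p[[part]][[s]]
    expect_true(any(bk$grads[[part]][[s]] != 0))
    for (i in sample(length(v), min(3, length(v)))) {
      e <- 1e-4
      pp <- p; pp[[part]][[s]][i] <- pp[[part]][[s]][i] + e
      pm <- p; pm[[part]][[s]][i] <- pm[[part]][[s]][i] - e
      expect_equal(bk$grads[[part]][[s]][i], (f(pp) - f(pm)) / (2 * e),
                   tolerance = 1e-4)
    }
  }
  ## input gradient too
  g <- bk$dx
  for (i in sample(length(x), 5)) {
    e <- 1e-4
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    num <- (sum(feamApply(xp, p)$y * r) - sum(feamApply(xm, p)$y * r)) /
      (2 * e)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("FEAM parameter count follows the closed form", {
  ## scales {30, 60}: 2 * (30^2 + 60^2) = 9000 spectral weights + gate
  expect_equal(feamParamCount(c(30, 60), 512, 4),
               9000 + 2 * 512 * 128 + 128 + 512)
  p <- feamInit(c(30L, 60L), 512L, reduction = 4L)
  expect_equal(sum(vapply(p$alpha, length, 1L)) +
                 sum(vapply(p$beta, length, 1L)), 9000)
  expect_equal(sum(lengths(p$gate)) + 9000, feamParamCount(c(30, 60), 512, 4))
})
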
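test_that("directional pooling returns exact axis means", {
  ## constant plane
  dp <- directionalPool(array(2.5, c(4, 6, 3)))
  expect_equal(dp$row, matrix(2.5, 4, 3))
  expect_equal(dp$col, matrix(2.5, 6, 3))
  ## single nonzero pixel: v/W in its row, v/H in its column
  x <- array(0, c(4, 4, 1))
  x[2, 3, 1] <- 8
  dp <- directionalPool(x)
  expect_equal(dp$row[, 1], c(0, 2, 0, 0))
  expect_equal(dp$col[, 1], c(0, 0, 2, 0))
  ## random plane vs naive double loop
  set.seed(31)
  y <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  dp <- directionalPool(y)
  for (ch in 1:2) for (i in 1:4) {
    expect_equal(dp$row[i, ch], mean(y[i, , ch]))
    expect_equal(dp$col[i, ch], mean(y[, i, ch]))
  }
})

test_that("EMA parameter count matches the closed form (g=8, C=1024)", {
  expect_equal(emaParamCount(1024, 8), 164352)
  ## and equals the printed ablation increment 31.196 - 31.031 = 0.165 M
  expect_equal(round(164352 / 1e6, 3), 0.164)
  p <- emaInit(1024, 8)
  expect_equal(sum(vapply(p, length, 1L)), 164352)
  base <- feswConfig(downsample = "maxpool", simam = FALSE, ema = FALSE,
                     feamCount = 0L)
  withEma <- feswConfig(downsample = "maxpool", simam = FALSE, ema = TRUE,
                        feamCount = 0L)
  expect_equal(nParameters(buildModel(withEma)) -
                 nParameters(buildModel(base)), 164352)
})

test_that("EMA preserves shape, maps zero to zero and bounds its gate", {
  set.seed(32)
  for (spec in list(c(64L, 4L), c(1024L, 8L))) {
    C <- spec[1]
    g <- spec[2]
    p <- emaInit(C, g)
    x <- randomFeature(4, 4, C, 1L)
    out <- emaApply(x, p, g)
    expect_equal(dim(out$y), dim(x))
    expect_true(all(is.finite(out$y)))
    ## the spatial modulation map is strictly inside (0, 1)
    gates <- vapply(out$cache$groupCaches,
                    function(cc) range(cc$s), numeric(2))
    expect_true(all(gates > 0 & gates < 1))
  }
  p <- emaInit(8, 2)
  z <- emaApply(array(0, c(4, 4, 8, 1)), p, 2)
  expect_equal(z$y, array(0, c(4, 4, 8, 1)))
  expect_error(emaApply(randomFeature(4, 4, 6), p, 4), "divisible")
})

test_that("permuting whole channel groups permutes the EMA output groups", {
  set.seed(33)
  C <- 12L
  g <- 3L
  cw <- C %/% g
  p <- emaInit(C, g)
  x <- randomFeature(5, 5, C, 1L)
  y <- emaApply(x, p, g)$y
  perm <- c(3L, 1L, 2L) # group-level permutation
  chPerm <- as.vector(vapply(perm, function(k) (k - 1L) * cw + seq_len(cw),
                             integer(cw)))
  yp <- emaApply(x[, , chPerm, , drop = FALSE], p, g)$y
  expect_equal(yp, y[, , chPerm, , drop = FALSE], tolerance = 1e-10)
})

test_that("EMA backward matches finite differences for all parameters", {
  set.seed(34)
  C <- 8
  g <- 2
  p <- emaInit(C, g)
  x <- randomFeature(5, 4, C, 2L, sd = 0.5)
  fw <- emaApply(x, p, g)
  r <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- emaBackward(p, fw$cache, r)
  f <- function(pp, xx) sum(emaApply(xx, pp, g)$y * r)
  for (i in sample(length(x), 6)) {
    e <- 1e-2
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    expect_equal(bk$dx[i], (f(p, xp) - f(p, xm)) / (2 * e),
                 tolerance = 2e-3)
  }
  for (nm in names(p)) {
    v <- p[[nm]]
    for (i in sample(length(v), min(4, length(v)))) {
      e <- 1e-3
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + e
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - e
      expect_equal(bk$grads[[nm]][i], (f(pp, x) - f(pm, x)) / (2 * e),
                   tolerance = 5e-3)
    }
  }
})
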
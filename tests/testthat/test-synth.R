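test_that("scenes are deterministic per seed and respect empty configs", {
  p <- sceneParams(size = 48L, seed = 9L)
  s1 <- synthScene(p)
  s2 <- synthScene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- synthScene(sceneParams(size = 48L, seed = 10L))
  expect_false(identical(s1$image, s3$image))
  ## no clusters -> all-background mask
  empty <- synthScene(sceneParams(size = 48L, nClusters = c(0L, 0L),
                                  seed = 1L))
  expect_equal(sum(empty$mask), 0)
  expect_true(is.null(empty$ellipses))
  ## invalid geometry rejected
  expect_error(sceneParams(size = 20L, aphidAxes = c(15, 30)), "larger")
})

test_that("image and mask are consistent, bounded and well-typed", {
  s <- synthScene(sceneParams(size = 64L, seed = 3L))
  expect_equal(dim(s$image), c(64L, 64L, 3L))
  expect_equal(dim(s$mask), c(64L, 64L))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_match(s$provenance, "^synthetic\\(seed=3\\)$")
})

test_that("mask area agrees with a Monte-Carlo ellipse-union oracle", {
  set.seed(61)
  fracMask <- 0
  fracMc <- 0
  for (seed in 1:50) {
    s <- synthScene(sceneParams(size = 64L, seed = seed))
    fracMask <- fracMask + mean(s$mask)
    ## Monte-Carlo union area from the generating ellipse parameters,
    ## independent of the rasteriser
    pts <- cbind(runif(4000, 0.5, 64.5), runif(4000, 0.5, 64.5))
    inside <- rep(FALSE, nrow(pts))
    if (!is.null(s$ellipses)) {
      for (i in seq_len(nrow(s$ellipses))) {
        e <- s$ellipses[i, ]
        dx <- pts[, 1] - e$cx
        dy <- pts[, 2] - e$cy
        u <- (dx * cos(e$phi) + dy * sin(e$phi)) / e$a
        v <- (-dx * sin(e$phi) + dy * cos(e$phi)) / e$b
        inside <- inside | (u * u + v * v <= 1)
      }
    }
    fracMc <- fracMc + mean(inside)
  }
  expect_lt(abs(fracMask - fracMc) / fracMc, 0.2)
})

test_that("augmentation doubles the set with one transform per subset", {
  set.seed(62)
  samples <- synthDataset(8, baseSeed = 100, size = 32)
  out <- augmentExpand(samples, seed = 5)
  expect_length(out, 16)
  prov <- vapply(out[9:16], `[[`, "", "provenance")
  tally <- table(sub("augmented\\((.*)\\)", "\\1", prov))
  expect_equal(sort(names(tally)),
               c("brightness", "horizontal_flip", "noise", "vertical_flip"))
  expect_true(all(tally == 2))
  ## flips are involutions on image and mask jointly
  for (k in 9:16) {
    orig <- out[[k - 8]]
    aug <- out[[k]]
    if (grepl("horizontal", aug$provenance)) {
      expect_identical(aug$image[, rev(seq_len(32)), , drop = FALSE],
                       orig$image)
      expect_identical(aug$mask[, rev(seq_len(32)), drop = FALSE], orig$mask)
    }
    if (grepl("vertical", aug$provenance)) {
      expect_identical(aug$image[rev(seq_len(32)), , , drop = FALSE],
                       orig$image)
    }
    ## brightness / noise leave masks bitwise unchanged
    if (grepl("brightness|noise", aug$provenance))
      expect_identical(aug$mask, orig$mask)
    expect_identical(dim(aug$image)[1:2], dim(aug$mask))
  }
  ## 612 originals expand to 1224 (the documented dataset protocol)
  fake <- rep(samples[1], 612)
  expect_length(augmentExpand(fake, seed = 1), 1224)
  expect_error(augmentExpand(list()), "non-empty")
})

test_that("train/test split is disjoint, exhaustive and seeded", {
  samples <- synthDataset(10, baseSeed = 1, size = 32)
  sp <- splitDataset(samples, ratio = 0.7, seed = 2)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  ids <- function(l) sort(vapply(l, `[[`, "", "id"))
  expect_equal(sort(c(ids(sp$train), ids(sp$test))), ids(samples))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- splitDataset(samples, ratio = 0.7, seed = 2)
  expect_equal(ids(sp2$train), ids(sp$train))
  expect_error(splitDataset(samples[1], 0.7, 1), "at least 2")
  expect_error(splitDataset(samples, 1.2, 1), "ratio")
})
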
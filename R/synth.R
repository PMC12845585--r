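#' Parameters of the synthetic field-scene generator
#'
#' Describes a synthetic sorghum-leaf scene with aphid clusters. The
#' generator emulates the difficulty axes of field imagery: a green leaf
#' base with sinusoidal vein striping, a directional illumination gradient,
#' optional cast shadow, Gaussian speckle noise, and low-contrast
#' elliptical aphid aggregations whose density and placement vary per
#' seed. Defaults describe a 480 x 480 scene (the working resolution for
#' field images); axis lengths are in pixels and scale with `size` if you
#' generate smaller scenes.
#'
#' @param size square image size in pixels.
#' @param nClusters range (min, max) of aphid clusters per scene; may be
#'   `c(0, 0)` for empty scenes.
#' @param aphidsPerCluster range of ellipses (individual aphids) per
#'   cluster.
#' @param aphidAxes range of ellipse semi-axis lengths in pixels.
#' @param clusterSpread standard deviation of aphid placement around the
#'   cluster centre, in pixels.
#' @param contrastOffset intensity offset of aphids against the leaf
#'   (small values give the characteristic low-contrast appearance).
#' @param veinAmplitude,veinFrequency amplitude (intensity units) and
#'   frequency (stripes per image) of the leaf-vein striping.
#' @param illuminationStrength peak-to-peak strength of the linear
#'   illumination gradient.
#' @param speckleSd standard deviation of the additive Gaussian speckle.
#' @param shadowProb probability of a cast shadow over half the scene.
#' @param seed integer seed; a scene is a deterministic function of
#'   `(params, seed)`.
#' @return list of class `"sceneParams"`.
#' @export
sceneParams <- function(size = 480L, nClusters = c(1L, 4L),
                        aphidsPerCluster = c(8L, 25L),
                        aphidAxes = c(4, 14) * size / 480,
                        clusterSpread = 18 * size / 480,
                        contrastOffset = 0.13,
                        veinAmplitude = 0.05, veinFrequency = 9,
                        illuminationStrength = 0.25,
                        speckleSd = 0.03, shadowProb = 0.3, seed = 1L) {
  p <- list(size = as.integer(size), nClusters = as.integer(nClusters),
            aphidsPerCluster = as.integer(aphidsPerCluster),
            aphidAxes = aphidAxes, clusterSpread = clusterSpread,
            contrastOffset = contrastOffset, veinAmplitude = veinAmplitude,
            veinFrequency = veinFrequency,
            illuminationStrength = illuminationStrength,
            speckleSd = speckleSd, shadowProb = shadowProb,
            seed = as.integer(seed))
  stopIf(any(unlist(p[c("aphidAxes", "clusterSpread", "contrastOffset",
                        "veinAmplitude", "veinFrequency",
                        "illuminationStrength", "speckleSd",
                        "shadowProb")]) < 0),
         "all magnitudes must be non-negative")
  stopIf(max(p$aphidAxes) * 2 > p$size,
         "aphid axes larger than the image")
  structure(p, class = "sceneParams")
}

#' Generate one synthetic aphid scene
#'
#' Renders the scene described by `p`: background = green base tone +
#' sinusoidal vein stripes (random orientation/phase) + linear illumination
#' gradient + Gaussian speckle (+ optional half-plane shadow); foreground =
#' the union of overlapping random ellipses per cluster, rendered at the
#' leaf tone shifted by the contrast offset. The mask is the exact ellipse
#' union. Bitwise deterministic given `(p, p$seed)`.
#'
#' @param p a [sceneParams()] list.
#' @return a segmentation sample: list with `image` (`size x size x 3`,
#'   values in `[0, 1]`), integer `mask` (`size x size`, 1 = aphid), `id`,
#'   `provenance` (`"synthetic(seed=...)"`) and the generating `ellipses`
#'   data frame (`cx, cy, a, b, phi`), exposed for geometric validation.
#' @export
synthScene <- function(p = sceneParams()) {
  stopIf(!inherits(p, "sceneParams"), "'p' must come from sceneParams()")
  withSeed(p$seed, {
    n <- p$size
    xs <- matrix(seq_len(n), n, n, byrow = TRUE) # column coordinate
    ys <- matrix(seq_len(n), n, n) # row coordinate
    base <- c(0.24, 0.47, 0.20)
    theta <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    veins <- p$veinAmplitude *
      sin(2 * pi * p$veinFrequency *
            (cos(theta) * xs + sin(theta) * ys) / n + phase)
    phiI <- runif(1, 0, 2 * pi)
    grad <- (cos(phiI) * (xs - n / 2) + sin(phiI) * (ys - n / 2)) / n
    illum <- p$illuminationStrength * grad
    shadow <- 0
    if (runif(1) < p$shadowProb) {
      sdir <- runif(1, 0, 2 * pi)
      shadow <- -0.12 * ((cos(sdir) * (xs - n / 2) +
                            sin(sdir) * (ys - n / 2)) > 0)
    }
    k <- if (p$nClusters[2L] >= p$nClusters[1L])
      sample(p$nClusters[1L]:p$nClusters[2L], 1L) else p$nClusters[1L]
    ell <- NULL
    mask <- matrix(FALSE, n, n)
    if (k > 0) {
      for (ci in seq_len(k)) {
        cx <- runif(1, 0.15 * n, 0.85 * n)
        cy <- runif(1, 0.15 * n, 0.85 * n)
        na <- sample(p$aphidsPerCluster[1L]:p$aphidsPerCluster[2L], 1L)
        ex <- rnorm(na, cx, p$clusterSpread)
        ey <- rnorm(na, cy, p$clusterSpread)
        ea <- runif(na, p$aphidAxes[1L], p$aphidAxes[2L])
        eb <- runif(na, p$aphidAxes[1L], p$aphidAxes[2L])
        ephi <- runif(na, 0, pi)
        ell <- rbind(ell, data.frame(cx = ex, cy = ey, a = ea, b = eb,
                                     phi = ephi))
      }
      ## clamp centres into the frame so clusters stay visible
      ell$cx <- pmin(pmax(ell$cx, 1), n)
      ell$cy <- pmin(pmax(ell$cy, 1), n)
      for (i in seq_len(nrow(ell))) {
        dx <- xs - ell$cx[i]
        dy <- ys - ell$cy[i]
        u <- (dx * cos(ell$phi[i]) + dy * sin(ell$phi[i])) / ell$a[i]
        v <- (-dx * sin(ell$phi[i]) + dy * cos(ell$phi[i])) / ell$b[i]
        mask <- mask | (u * u + v * v <= 1)
      }
    }
    img <- array(0, c(n, n, 3L))
    dark <- runif(1) < 0.5 # aphids darker or paler than the leaf
    off <- if (dark) -p$contrastOffset else p$contrastOffset
    for (ch in 1:3) {
      plane <- base[ch] + veins * (if (ch == 2) 1 else 0.5) + illum + shadow
      plane <- plane + off * mask * (1 + 0.1 * (ch == 1)) # brownish tint
      plane <- plane + matrix(rnorm(n * n, 0, p$speckleSd), n, n)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    list(image = img, mask = matrix(as.integer(mask), n, n),
         id = sprintf("synthetic-%d", p$seed),
         provenance = sprintf("synthetic(seed=%d)", p$seed),
         ellipses = ell)
  })
}

#' Generate a list of synthetic scenes
#'
#' Convenience wrapper producing `n` scenes from consecutive seeds
#' (`baseSeed`, `baseSeed + 1`, ...), sharing all other parameters.
#'
#' @param n number of scenes.
#' @param baseSeed first seed.
#' @param ... arguments forwarded to [sceneParams()].
#' @return list of segmentation samples.
#' @export
synthDataset <- function(n, baseSeed = 1L, ...) {
  lapply(seq_len(n), function(i)
    synthScene(sceneParams(..., seed = baseSeed + i - 1L)))
}

#' Double a dataset by subset-wise augmentation
#'
#' Reproduces the expansion protocol used to build the field dataset: the
#' samples are randomly partitioned (seeded) into four equal, non-
#' overlapping subsets, and every image receives exactly one additional
#' transformed copy according to its subset -- horizontal flip, vertical
#' flip, multiplicative brightness perturbation (factor uniform in
#' `[0.7, 1.3]`), or additive Gaussian noise (sd 5% of the dynamic range).
#' Flips are applied jointly to image and mask; brightness and noise touch
#' the image only, leaving the mask bitwise unchanged. The output holds
#' the originals followed by the transformed copies (twice the input
#' length). If the length is not divisible by 4, the first `n mod 4`
#' subsets take one extra sample each.
#'
#' @param samples non-empty list of segmentation samples.
#' @param seed integer seed for the partition and the perturbation draws.
#' @param brightnessRange,noiseSd transform magnitudes (configurable).
#' @return list of length `2 * length(samples)`; transformed copies carry
#'   provenance `"augmented(<transform>)"`.
#' @export
augmentExpand <- function(samples, seed = 1L,
                          brightnessRange = c(0.7, 1.3), noiseSd = 0.05) {
  stopIf(length(samples) == 0L, "'samples' must be non-empty")
  transforms <- c("horizontal_flip", "vertical_flip", "brightness", "noise")
  n <- length(samples)
  withSeed(seed, {
    ord <- sample(n)
    sizes <- rep(n %/% 4L, 4L)
    if (n %% 4L > 0L) sizes[seq_len(n %% 4L)] <- sizes[seq_len(n %% 4L)] + 1L
    assign <- rep(transforms, times = sizes)[order(ord)]
    aug <- vector("list", n)
    for (i in seq_len(n)) {
      s <- samples[[i]]
      tr <- assign[i]
      out <- s
      if (tr == "horizontal_flip") {
        out$image <- s$image[, rev(seq_len(ncol(s$mask))), , drop = FALSE]
        out$mask <- s$mask[, rev(seq_len(ncol(s$mask))), drop = FALSE]
      } else if (tr == "vertical_flip") {
        out$image <- s$image[rev(seq_len(nrow(s$mask))), , , drop = FALSE]
        out$mask <- s$mask[rev(seq_len(nrow(s$mask))), , drop = FALSE]
      } else if (tr == "brightness") {
        f <- runif(1, brightnessRange[1L], brightnessRange[2L])
        out$image <- pmin(pmax(s$image * f, 0), 1)
      } else {
        out$image <- pmin(pmax(s$image +
          array(rnorm(length(s$image), 0, noiseSd), dim(s$image)), 0), 1)
      }
      out$id <- paste0(s$id, "-aug")
      out$provenance <- sprintf("augmented(%s)", tr)
      aug[[i]] <- out
    }
    c(samples, aug)
  })
}

#' Seeded train/test split
#'
#' Shuffles the samples under the given seed and splits them exhaustively
#' and disjointly; the training set takes `ceiling(ratio * n)` samples and
#' the test set the remainder.
#'
#' @param samples list of at least 2 samples.
#' @param ratio training fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` sample lists.
#' @export
splitDataset <- function(samples, ratio = 0.7, seed = 1L) {
  stopIf(length(samples) < 2L, "need at least 2 samples to split")
  stopIf(ratio <= 0 || ratio >= 1, "'ratio' must be in (0, 1)")
  withSeed(seed, {
    ord <- sample(length(samples))
    nTrain <- ceiling(ratio * length(samples))
    list(train = samples[sort(ord[seq_len(nTrain)])],
         test = samples[sort(ord[-seq_len(nTrain)])])
  })
}
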
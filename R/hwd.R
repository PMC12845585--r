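#' Single-level 2-D Haar wavelet decomposition
#'
#' Decomposes a feature map into the four orthonormal Haar subbands --
#' approximation (A), horizontal detail, vertical detail and diagonal
#' detail -- each at half the spatial resolution, stacked along the channel
#' dimension in that order (all A channels first, then all horizontal, ...).
#' With the orthonormal \eqn{1/\sqrt{2}} filters each non-overlapping 2x2
#' block `[[a, b], [c, d]]` maps to
#' `A = (a+b+c+d)/2`, `horiz = (a-b+c-d)/2`, `vert = (a+b-c-d)/2`,
#' `diag = (a-b-c+d)/2`. "Horizontal detail" is the response of the
#' high-pass filter applied along the width axis. The transform is
#' orthonormal: it conserves the sum of squares exactly and is inverted
#' losslessly by [haarIdwt()].
#'
#' @param x numeric array `(H, W, C)` or `(H, W, C, N)` with even `H` and
#'   `W`. No implicit padding is performed; odd dimensions are an error.
#' @return array `(H/2, W/2, 4C)` (or `(H/2, W/2, 4C, N)`) of subband
#'   coefficients.
#' @seealso [haarIdwt()], [hwdApply()]
#' @export
haarDwt <- function(x) {
  nd <- length(dim(x))
  stopIf(!(nd %in% c(3L, 4L)), "'x' must be an (H,W,C) or (H,W,C,N) array")
  x3 <- nd == 3L
  x <- asBatch(x)
  d <- dim(x)
  stopIf(d[1L] %% 2L != 0L || d[2L] %% 2L != 0L,
         "Haar downsampling requires even spatial dimensions, got ",
         d[1L], "x", d[2L])
  oi <- seq(1L, d[1L], 2L)
  oj <- seq(1L, d[2L], 2L)
  a <- x[oi, oj, , , drop = FALSE]
  b <- x[oi, oj + 1L, , , drop = FALSE]
  cc <- x[oi + 1L, oj, , , drop = FALSE]
  dd <- x[oi + 1L, oj + 1L, , , drop = FALSE]
  out <- array(0, c(d[1L] / 2L, d[2L] / 2L, 4L * d[3L], d[4L]))
  ch <- seq_len(d[3L])
  out[, , ch, ] <- (a + b + cc + dd) / 2
  out[, , ch + d[3L], ] <- (a - b + cc - dd) / 2
  out[, , ch + 2L * d[3L], ] <- (a + b - cc - dd) / 2
  out[, , ch + 3L * d[3L], ] <- (a - b - cc + dd) / 2
  if (x3) dim(out) <- dim(out)[1:3]
  out
}

#' Inverse single-level 2-D Haar transform
#'
#' Reconstructs the original feature map from a `4C`-channel subband stack
#' produced by [haarDwt()] (same subband ordering). The round trip
#' `haarIdwt(haarDwt(x))` reproduces `x` to floating-point accuracy.
#'
#' @param s subband array `(H/2, W/2, 4C)` or `(H/2, W/2, 4C, N)`; the
#'   channel count must be a multiple of 4.
#' @return array `(H, W, C)` (or batched).
#' @export
haarIdwt <- function(s) {
  nd <- length(dim(s))
  stopIf(!(nd %in% c(3L, 4L)), "'s' must be a 3- or 4-d array")
  x3 <- nd == 3L
  s <- asBatch(s)
  d <- dim(s)
  stopIf(d[3L] %% 4L != 0L,
         "subband stack must have a channel count divisible by 4")
  C <- d[3L] %/% 4L
  ch <- seq_len(C)
  A <- s[, , ch, , drop = FALSE]
  Hh <- s[, , ch + C, , drop = FALSE]
  V <- s[, , ch + 2L * C, , drop = FALSE]
  D <- s[, , ch + 3L * C, , drop = FALSE]
  out <- array(0, c(2L * d[1L], 2L * d[2L], C, d[4L]))
  oi <- seq(1L, 2L * d[1L], 2L)
  oj <- seq(1L, 2L * d[2L], 2L)
  out[oi, oj, , ] <- (A + Hh + V + D) / 2
  out[oi, oj + 1L, , ] <- (A - Hh + V - D) / 2
  out[oi + 1L, oj, , ] <- (A + Hh - V - D) / 2
  out[oi + 1L, oj + 1L, , ] <- (A - Hh - V + D) / 2
  if (x3) dim(out) <- dim(out)[1:3]
  out
}

#' Haar-wavelet downsampling block (HWD)
#'
#' Functional form of the downsampling block that replaces max-pooling:
#' a lossless Haar decomposition (zero parameters) followed by a learned
#' representation head -- 1x1 convolution (`4C -> outChannels`, with bias),
#' batch normalisation and ReLU. Output spatial dimensions are exactly
#' halved and all values are non-negative.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`, even `H`, `W`.
#' @param params list with elements `W` (`1 x 1 x 4C x outChannels` conv
#'   weights), `b`, `gamma`, `beta` as produced by [buildModel()] for each
#'   downsampling position.
#' @param buffers batch-norm running statistics (`mean`, `var`).
#' @param training logical; use batch statistics (TRUE) or running
#'   statistics (FALSE).
#' @return list with the output feature map `y`, the possibly updated
#'   `buffers`, and a `cache` for the backward pass.
#' @export
hwdApply <- function(x, params, buffers, training = FALSE) {
  x <- asBatch(x)
  s <- haarDwt(x)
  if (!training) {
    a <- params$gamma / sqrt(buffers$var + 1e-5)
    sh <- params$beta - buffers$mean * a
    y <- convForward(s, params$W, params$b, postA = a, postB = sh,
                     relu = TRUE)
    return(list(y = y, buffers = buffers, cache = NULL))
  }
  z <- convForward(s, params$W, params$b)
  bn <- bnForward(z, params$gamma, params$beta, buffers, training)
  y <- reluForward(bn$y)
  list(y = y, buffers = bn$buffers,
       cache = list(s = s, z = bn$y, bn = bn$cache))
}

hwdBackward <- function(params, cache, dy) {
  dz <- reluBackward(cache$z, dy)
  bb <- bnBackward(cache$bn, dz)
  cv <- convBackward(cache$s, params$W, bb$dx, needDx = TRUE)
  ## adjoint of an orthonormal transform is its inverse
  list(dx = haarIdwt(cv$dx),
       grads = list(W = cv$dw, b = cv$db, gamma = bb$dgamma, beta = bb$dbeta))
}
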
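## Primitive differentiable tensor operations backing the network layers.
## All operate on (H, W, C, N) arrays. Forward functions return the output
## (plus whatever cache the matching backward needs); backward functions
## take the upstream gradient and return input/parameter gradients.
## Convolutions call the compiled im2col/GEMM kernels (float32 compute).

convForward <- function(x, w, b, postA = numeric(0), postB = numeric(0),
                        relu = FALSE) {
  k <- dim(w)[1L]
  cpp_conv2d_fwd(x, dim(x), w, b, k, (k - 1L) %/% 2L, postA, postB, relu)
}

convBackward <- function(x, w, dy, needDx = TRUE) {
  k <- dim(w)[1L]
  cpp_conv2d_bwd(x, dim(x), w, dy, k, (k - 1L) %/% 2L, needDx)
}

## 2x2 stride-2 transposed convolution (the U-Net up-sampling step).
## Weight layout: (2, 2, Cout, Cin); each input pixel paints a 2x2 block.
convTransposeForward <- function(x, w, b) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  Cout <- dim(w)[3L]
  Wm <- matrix(w, 4L * Cout, Cin) # rows: (di, dj, co)
  y <- array(0, c(2L * H, 2L * W, Cout, N))
  for (n in seq_len(N)) {
    Xm <- matrix(x[, , , n], H * W, Cin)
    Ym <- tcrossprod(Xm, Wm) # (HW) x (4*Cout)
    arr <- array(Ym, c(H, W, 2L, 2L, Cout))
    arr <- aperm(arr, c(3L, 1L, 4L, 2L, 5L))
    dim(arr) <- c(2L * H, 2L * W, Cout)
    y[, , , n] <- arr + rep(b, each = 4L * H * W)
  }
  y
}

convTransposeBackward <- function(x, w, dy) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  Cout <- dim(w)[3L]
  Wm <- matrix(w, 4L * Cout, Cin)
  dx <- array(0, d)
  dW <- matrix(0, 4L * Cout, Cin)
  db <- numeric(Cout)
  for (n in seq_len(N)) {
    arr <- array(dy[, , , n], c(2L, H, 2L, W, Cout))
    db <- db + .colSums(matrix(arr, 4L * H * W, Cout), 4L * H * W, Cout)
    arr <- aperm(arr, c(2L, 4L, 1L, 3L, 5L)) # (H, W, di, dj, co)
    dYm <- matrix(arr, H * W, 4L * Cout)
    Xm <- matrix(x[, , , n], H * W, Cin)
    dx[, , , n] <- array(dYm %*% Wm, c(H, W, Cin))
    dW <- dW + crossprod(dYm, Xm)
  }
  list(dx = dx, dw = array(dW, dim(w)), db = db)
}

reluForward <- function(x) pmax(x, 0)
reluBackward <- function(x, dy) dy * (x > 0)

## Batch normalization over (H, W, N) per channel. `training` switches
## between batch statistics (with running-stat update) and stored running
## statistics. Returns list(y, cache, buffers).
bnForward <- function(x, gamma, beta, buffers, training, eps = 1e-5,
                      momentum = 0.1) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  nt <- hw * d[4L]
  if (training) {
    s <- rowSums(planeSums(x))
    s2 <- rowSums(planeSums(x * x))
    mu <- s / nt
    v <- pmax(s2 / nt - mu^2, 0)
    ub <- if (nt > 1L) nt / (nt - 1L) else 1
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var + momentum * v * ub
  } else {
    mu <- buffers$mean
    v <- buffers$var
  }
  invstd <- 1 / sqrt(v + eps)
  a <- gamma * invstd
  y <- x * rep(a, each = hw) + rep(beta - mu * a, each = hw)
  list(y = y, cache = list(x = x, mu = mu, invstd = invstd, gamma = gamma),
       buffers = buffers)
}

bnBackward <- function(cache, dy) {
  x <- cache$x
  d <- dim(x)
  hw <- d[1L] * d[2L]
  nt <- hw * d[4L]
  xhat <- (x - rep(cache$mu, each = hw)) * rep(cache$invstd, each = hw)
  sdy <- rowSums(planeSums(dy))
  sdyx <- rowSums(planeSums(dy * xhat))
  dgamma <- sdyx
  dbeta <- sdy
  a <- cache$gamma * cache$invstd
  dx <- rep(a / nt, each = hw) *
    (nt * dy - rep(sdy, each = hw) - xhat * rep(sdyx, each = hw))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## Inference-mode batch norm gradient is not needed; training always uses
## batch statistics.

maxpoolForward <- function(x) {
  d <- dim(x)
  stopIf(d[1L] %% 2L != 0L || d[2L] %% 2L != 0L,
         "max-pooling requires even spatial dimensions")
  oi <- seq(1L, d[1L], 2L)
  oj <- seq(1L, d[2L], 2L)
  a <- x[oi, oj, , , drop = FALSE]
  b <- x[oi, oj + 1L, , , drop = FALSE]
  cc <- x[oi + 1L, oj, , , drop = FALSE]
  dd <- x[oi + 1L, oj + 1L, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  wa <- a == m
  wb <- (b == m) & !wa
  wc <- (cc == m) & !wa & !wb
  wd <- !wa & !wb & !wc
  list(y = m, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dim = d))
}

maxpoolBackward <- function(cache, dy) {
  d <- cache$dim
  dx <- array(0, d)
  oi <- seq(1L, d[1L], 2L)
  oj <- seq(1L, d[2L], 2L)
  dx[oi, oj, , ] <- dy * cache$wa
  dx[oi, oj + 1L, , ] <- dy * cache$wb
  dx[oi + 1L, oj, , ] <- dy * cache$wc
  dx[oi + 1L, oj + 1L, , ] <- dy * cache$wd
  dx
}

## Batched 2-D FFT helpers: transform each (H, W) plane of an (H, W, C, N)
## array. Implemented with two passes of mvfft over reshaped views.
fft2Batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; rest <- prod(d[-c(1L, 2L)])
  z <- mvfft(matrix(x, H, W * rest), inverse = inverse)
  z <- array(z, c(H, W, rest))
  z <- aperm(z, c(2L, 1L, 3L))
  z <- mvfft(matrix(z, W, H * rest), inverse = inverse)
  z <- aperm(array(z, c(W, H, rest)), c(2L, 1L, 3L))
  dim(z) <- d
  if (inverse) z / (H * W) else z
}
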
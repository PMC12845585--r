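#' Project a learnable spectral weight grid to a feature-map resolution
#'
#' Bilinearly interpolates a stored `s x s` weight grid (real or imaginary
#' part of a complex spectral filter) to the `H x W` resolution of the
#' hosting feature map, using the align-corners convention (corner samples
#' map onto corner positions). Projection is the exact identity when the
#' target equals the stored grid size, and constants are preserved.
#'
#' @param grid numeric matrix (the stored weight grid).
#' @param H,W target spatial dimensions (positive integers).
#' @return `H x W` numeric matrix.
#' @export
feamProjectWeights <- function(grid, H, W) {
  stopIf(!is.matrix(grid), "'grid' must be a matrix")
  stopIf(H < 1 || W < 1, "target dimensions must be >= 1")
  if (all(dim(grid) == c(H, W))) return(grid)
  bilinearMatrix(H, nrow(grid)) %*% grid %*% t(bilinearMatrix(W, ncol(grid)))
}

#' Spectral (frequency-domain) feature modulation
#'
#' Multiplies the unitary 2-D Fourier transform of every channel plane by
#' the complex filter `alpha + i beta` and maps back to the spatial domain,
#' keeping the real part:
#' \deqn{X_{freq} = \Re\,\mathcal{F}^{-1}\big(\mathcal{F}(X) \odot
#'   (\tilde\alpha + j\tilde\beta)\big).}
#' The filter is broadcast identically to all channels. Frequency bins
#' follow the FFT's native ordering with the zero-frequency (DC) bin at
#' index (1, 1); no fftshift is applied, and weight grids are defined in
#' that ordering. `alpha = 1`, `beta = 0` is the exact identity.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param alpha,beta real `H x W` matrices (projected filter parts).
#' @return array of the same shape as `x` (real-valued).
#' @export
freqModulate <- function(x, alpha, beta) {
  nd <- length(dim(x))
  stopIf(!(nd %in% c(3L, 4L)), "'x' must be an (H,W,C) or (H,W,C,N) array")
  d <- dim(x)
  stopIf(!all(dim(alpha) == d[1:2]) || !all(dim(beta) == d[1:2]),
         "filter dimensions must match the spatial dimensions of 'x'")
  wv <- as.vector(complex(real = alpha, imaginary = beta))
  z <- fft2Batch(asBatch(x)) * wv # recycled over channels/samples
  y <- Re(fft2Batch(z, inverse = TRUE))
  dim(y) <- d
  y
}

#' Spatial pixel gate
#'
#' Scales every pixel of a feature map by the (projected) real part of the
#' spectral filter, broadcast over channels, so that all channels at the
#' same location are modulated consistently: `X_sp = alpha * X`.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param alpha real `H x W` matrix.
#' @return array of the same shape as `x`.
#' @export
spatialGate <- function(x, alpha) {
  d <- dim(x)
  stopIf(!all(dim(alpha) == d[1:2]),
         "'alpha' dimensions must match the spatial dimensions of 'x'")
  x * as.vector(alpha)
}

#' Fuse per-scale dual-domain branches
#'
#' Averages the summed frequency- and spatial-branch outputs over scales:
#' `Y = (1/|S|) * sum_s (X_s_freq + X_s_sp)`. With identity weights every
#' branch pair sums to `2X`, so the fused map is `2X` for any scale set.
#'
#' @param branches non-empty list; each element a list with components
#'   `freq` and `sp` of identical shape.
#' @return array of the common shape.
#' @export
fuseScales <- function(branches) {
  stopIf(length(branches) == 0L, "'branches' must be a non-empty list")
  acc <- branches[[1L]]$freq + branches[[1L]]$sp
  for (b in branches[-1L]) acc <- acc + b$freq + b$sp
  acc / length(branches)
}

#' Channel attention gate
#'
#' Computes a per-channel importance vector in (0, 1) from global average-
#' and max-pooled channel descriptors passed through a shared two-layer
#' bottleneck (`C -> C/r -> C`, ReLU in between, biases on; the output bias
#' is added once to the summed pathways) and a sigmoid, then re-weights the
#' channels: `X_final = Y * g(Y)`.
#'
#' @param y feature map `(H, W, C)` or `(H, W, C, N)` with `C >= reduction`.
#' @param params list with `W1` (`C/r x C`), `b1`, `W2` (`C x C/r`), `b2`.
#' @param keepCache logical; retain intermediates for the backward pass.
#' @return list with gated output `y`, the gate values `gate` (`C x N`
#'   matrix) and (optionally) a `cache`.
#' @export
channelGate <- function(y, params, keepCache = FALSE) {
  nd <- length(dim(y))
  x3 <- nd == 3L
  y <- asBatch(y)
  d <- dim(y)
  stopIf(d[3L] != ncol(params$W1),
         "channel count ", d[3L], " does not match the gate (built for ",
         ncol(params$W1), " channels)")
  hw <- d[1L] * d[2L]
  ym <- matrix(y, hw, d[3L] * d[4L])
  da <- matrix(.colSums(ym, hw, d[3L] * d[4L]) / hw, d[3L], d[4L])
  idx <- apply(ym, 2L, which.max)
  dm <- matrix(ym[cbind(idx, seq_along(idx))], d[3L], d[4L])
  za <- params$W1 %*% da + params$b1
  zm <- params$W1 %*% dm + params$b1
  ha <- pmax(za, 0)
  hm <- pmax(zm, 0)
  u <- params$W2 %*% (ha + hm) + params$b2
  g <- sigmoid(u)
  out <- y * broadcastCN(g, hw)
  if (x3) dim(out) <- d[1:3]
  res <- list(y = out, gate = g)
  if (keepCache)
    res$cache <- list(yin = y, da = da, dm = dm, idx = idx, za = za, zm = zm,
                      ha = ha, hm = hm, g = g, dim = d)
  res
}

channelGateBackward <- function(params, cache, dout) {
  d <- cache$dim
  hw <- d[1L] * d[2L]
  y <- cache$yin
  g <- cache$g
  dg <- planeSums(dout * y)
  dy <- dout * broadcastCN(g, hw)
  du <- dg * g * (1 - g)
  dW2 <- du %*% t(cache$ha + cache$hm)
  db2 <- rowSums(du)
  dh <- crossprod(params$W2, du)
  dza <- dh * (cache$za > 0)
  dzm <- dh * (cache$zm > 0)
  dW1 <- dza %*% t(cache$da) + dzm %*% t(cache$dm)
  db1 <- rowSums(dza + dzm)
  dda <- crossprod(params$W1, dza)
  ddm <- crossprod(params$W1, dzm)
  dy <- dy + broadcastCN(dda, hw) / hw
  ## scatter max-pool gradient to the arg-max positions
  dym <- matrix(dy, hw, d[3L] * d[4L])
  dym[cbind(cache$idx, seq_along(cache$idx))] <-
    dym[cbind(cache$idx, seq_along(cache$idx))] + as.vector(ddm)
  dy <- array(dym, d)
  list(dy = dy, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Fourier-enhanced attention module (FEAM)
#'
#' Full skip-connection block: for every scale `s` the stored complex
#' weight grid is projected to the feature resolution, the feature map is
#' modulated in the frequency domain ([freqModulate()]) and gated in the
#' spatial domain ([spatialGate()]); the branch outputs are fused across
#' scales ([fuseScales()]) and finally re-weighted per channel
#' ([channelGate()]). Shape-preserving. With the identity initialisation
#' (`alpha = 1`, `beta = 0`) the pre-gate fusion equals `2 X` exactly.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`; every stored scale
#'   must not exceed `min(H, W)`.
#' @param params list with `alpha` (list of `s x s` matrices), `beta`
#'   (matching list) and `gate` (channel-gate parameters), as created by
#'   `feamInit()` / [buildModel()].
#' @param keepCache logical; retain intermediates for the backward pass.
#' @return list with output `y` (same shape as `x`), the pre-gate fused
#'   map `fused`, and (optionally) a `cache`.
#' @export
feamApply <- function(x, params, keepCache = FALSE) {
  nd <- length(dim(x))
  x3 <- nd == 3L
  x <- asBatch(x)
  d <- dim(x)
  scales <- vapply(params$alpha, nrow, 1L)
  stopIf(any(scales > min(d[1:2])),
         "FEAM scales (", paste(scales, collapse = ", "),
         ") exceed the hosting feature map size ", d[1L], "x", d[2L])
  Xf <- fft2Batch(x)
  nS <- length(params$alpha)
  branches <- vector("list", nS)
  proj <- vector("list", nS)
  for (s in seq_len(nS)) {
    at <- feamProjectWeights(params$alpha[[s]], d[1L], d[2L])
    bt <- feamProjectWeights(params$beta[[s]], d[1L], d[2L])
    wv <- as.vector(complex(real = at, imaginary = bt))
    fr <- Re(fft2Batch(array(Xf * wv, d), inverse = TRUE))
    branches[[s]] <- list(freq = fr, sp = x * as.vector(at))
    proj[[s]] <- list(at = at, bt = bt)
  }
  fused <- fuseScales(branches)
  cg <- channelGate(fused, params$gate, keepCache = keepCache)
  y <- cg$y
  if (x3) dim(y) <- d[1:3]
  res <- list(y = y, fused = fused, gate = cg$gate)
  if (keepCache)
    res$cache <- list(x = x, Xf = Xf, proj = proj, gateCache = cg$cache,
                      dim = d)
  res
}

## Identity (alpha = 1, beta = 0) or small-random FEAM parameters for a pair
## of nominal scales at a skip with `channels` channels.
feamInit <- function(scales, channels, reduction = 4L,
                     init = c("identity", "random")) {
  init <- match.arg(init)
  stopIf(reduction > channels,
         "gate reduction ", reduction, " exceeds channel count ", channels)
  mk <- function(s, val) matrix(val, s, s)
  alpha <- lapply(scales, function(s)
    if (init == "identity") mk(s, 1) else matrix(rnorm(s * s, 1, 0.02), s, s))
  beta <- lapply(scales, function(s)
    if (init == "identity") mk(s, 0) else matrix(rnorm(s * s, 0, 0.02), s, s))
  cr <- channels %/% reduction
  gate <- list(W1 = matrix(rnorm(cr * channels) * sqrt(2 / channels),
                           cr, channels),
               b1 = numeric(cr),
               W2 = matrix(rnorm(channels * cr) * sqrt(2 / cr), channels, cr),
               b2 = numeric(channels))
  list(alpha = alpha, beta = beta, gate = gate)
}

feamParamCount <- function(scales, channels, reduction = 4L) {
  2 * sum(scales^2) + 2 * channels * (channels %/% reduction) +
    (channels %/% reduction) + channels
}

## Reverse-mode gradient of feamApply. The frequency branch is linear in x
## with adjoint Re(F^-1(F(dy) . conj(W))); the spectral weight gradients
## follow from d/dA Re(F^-1(X^ . (A + iB))) contracted with the upstream
## gradient, summed over channels and samples, then pulled through the
## bilinear projection adjoint.
feamBackward <- function(params, cache, dy) {
  d <- cache$dim
  hw <- d[1L] * d[2L]
  cn <- d[3L] * d[4L]
  gb <- channelGateBackward(params$gate, cache$gateCache, asBatch(dy))
  dfused <- gb$dy
  nS <- length(params$alpha)
  dx <- array(0, d)
  dalpha <- vector("list", nS)
  dbeta <- vector("list", nS)
  dbr <- dfused / nS
  Fdy <- fft2Batch(dbr)
  for (s in seq_len(nS)) {
    at <- cache$proj[[s]]$at
    bt <- cache$proj[[s]]$bt
    wv <- as.vector(complex(real = at, imaginary = bt))
    ## input gradient: spatial branch + frequency-branch adjoint
    dx <- dx + dbr * as.vector(at) +
      Re(fft2Batch(array(Fdy * Conj(wv), d), inverse = TRUE))
    ## filter gradients at full resolution
    prodv <- cache$Xf * Conj(Fdy)
    reSum <- matrix(.rowSums(matrix(Re(prodv), hw, cn), hw, cn), d[1L], d[2L])
    imSum <- matrix(.rowSums(matrix(Im(prodv), hw, cn), hw, cn), d[1L], d[2L])
    datFull <- reSum / hw +
      matrix(.rowSums(matrix(cache$x * dbr, hw, cn), hw, cn), d[1L], d[2L])
    dbtFull <- -imSum / hw
    Rh <- bilinearMatrix(d[1L], nrow(params$alpha[[s]]))
    Rw <- bilinearMatrix(d[2L], ncol(params$alpha[[s]]))
    dalpha[[s]] <- crossprod(Rh, datFull) %*% Rw
    dbeta[[s]] <- crossprod(Rh, dbtFull) %*% Rw
  }
  list(dx = dx,
       grads = list(alpha = dalpha, beta = dbeta, gate = gb$grads))
}
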
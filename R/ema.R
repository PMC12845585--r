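#' Directional (strip) average pooling
#'
#' One-dimensional global average pooling along each spatial axis of a
#' per-group feature map: the row descriptor averages over the width for
#' every (row, channel) pair and the column descriptor averages over the
#' height for every (column, channel) pair. These anisotropic descriptors
#' feed the 1x1 pathway of the EMA block.
#'
#' @param x numeric array `(H, W, c)`.
#' @return list with `row` (`H x c` matrix, averages along width) and
#'   `col` (`W x c` matrix, averages along height).
#' @export
directionalPool <- function(x) {
  stopIf(length(dim(x)) != 3L, "'x' must be an (H, W, c) array")
  d <- dim(x)
  row <- matrix(.colSums(aperm(x, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L]),
                d[1L], d[3L]) / d[2L]
  col <- matrix(.colSums(x, d[1L], d[2L] * d[3L]), d[2L], d[3L]) / d[1L]
  list(row = row, col = col)
}

#' Efficient multi-scale attention (EMA)
#'
#' Applies the EMA block: channels are partitioned into `groups` groups of
#' width `c = C / groups`; within each group a 1x1 pathway (on concatenated
#' directional pools, split and re-applied through sigmoids, followed by
#' per-channel group normalisation) and a 3x3 pathway run in parallel, and
#' their cross-spatial aggregation -- softmax-weighted channel descriptors of
#' one branch contracted against the spatial maps of the other -- yields a
#' single spatial map per group that re-scales the group through a final
#' sigmoid. Output shape equals input shape and the modulation is bounded
#' in (0, 1). Learnable parameters: one `c -> c` 1x1 convolution, one
#' `c -> c` 3x3 convolution and an affine per-channel normalisation
#' (`(c^2 + c) + (9 c^2 + c) + 2c` parameters in total, shared by all
#' groups).
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param params list with `w1`, `b1` (1x1 conv, `(1,1,c,c)` and `c`),
#'   `w3`, `b3` (3x3 conv), `gamma`, `beta` (normalisation affine), as
#'   created by [buildModel()] or `emaInit()`.
#' @param groups number of channel groups; must divide `C`.
#' @return list with output `y` (same shape as `x`) and a `cache` for the
#'   backward pass.
#' @export
emaApply <- function(x, params, groups) {
  nd <- length(dim(x))
  stopIf(!(nd %in% c(3L, 4L)), "'x' must be an (H,W,C) or (H,W,C,N) array")
  x3 <- nd == 3L
  x <- asBatch(x)
  d <- dim(x)
  stopIf(d[3L] %% groups != 0L,
         "channel count ", d[3L], " is not divisible by groups = ", groups)
  cw <- d[3L] %/% groups
  y <- array(0, d)
  caches <- vector("list", d[4L] * groups)
  k <- 0L
  for (n in seq_len(d[4L])) {
    for (g in seq_len(groups)) {
      ch <- ((g - 1L) * cw + 1L):(g * cw)
      gx <- array(x[, , ch, n], c(d[1L], d[2L], cw))
      fg <- emaGroupForward(gx, params)
      y[, , ch, n] <- fg$y
      k <- k + 1L
      caches[[k]] <- fg$cache
    }
  }
  if (x3) dim(y) <- d[1:3]
  list(y = y, cache = list(groupCaches = caches, groups = groups, dim = d))
}

## EMA parameter initialiser (He-normal convs, unit affine).
emaInit <- function(channels, groups) {
  cw <- channels %/% groups
  list(w1 = array(rnorm(cw * cw) * sqrt(2 / cw), c(1L, 1L, cw, cw)),
       b1 = numeric(cw),
       w3 = array(rnorm(9 * cw * cw) * sqrt(2 / (9 * cw)), c(3L, 3L, cw, cw)),
       b3 = numeric(cw),
       gamma = rep(1, cw), beta = numeric(cw))
}

emaParamCount <- function(channels, groups) {
  cw <- channels %/% groups
  (cw^2 + cw) + (9 * cw^2 + cw) + 2 * cw
}

## Forward pass for one channel group (gx: (H, W, c)).
emaGroupForward <- function(gx, params) {
  d <- dim(gx)
  H <- d[1L]; W <- d[2L]; cw <- d[3L]
  dp <- directionalPool(gx)
  W1 <- matrix(params$w1, cw, cw)
  z <- rbind(dp$row, dp$col) %*% W1 +
    matrix(params$b1, H + W, cw, byrow = TRUE)
  zh <- z[seq_len(H), , drop = FALSE]
  zw <- z[H + seq_len(W), , drop = FALSE]
  sh <- sigmoid(zh)
  sw <- sigmoid(zw)
  th <- aperm(array(sh, c(H, cw, W)), c(1L, 3L, 2L)) # (H,W,c) broadcast of sh
  tw <- aperm(array(sw, c(W, cw, H)), c(3L, 1L, 2L))
  x1pre <- gx * th * tw
  ## per-channel (instance) normalisation with affine parameters
  m1 <- .colSums(x1pre, H * W, cw) / (H * W)
  v1 <- .colSums(x1pre^2, H * W, cw) / (H * W) - m1^2
  invstd <- 1 / sqrt(pmax(v1, 0) + 1e-5)
  xhat <- (x1pre - rep(m1, each = H * W)) * rep(invstd, each = H * W)
  x1 <- xhat * rep(params$gamma, each = H * W) + rep(params$beta, each = H * W)
  x2 <- convForward(array(gx, c(H, W, cw, 1L)), params$w3, params$b3)
  dim(x2) <- c(H, W, cw)
  p1 <- .colSums(x1, H * W, cw) / (H * W)
  p2 <- .colSums(x2, H * W, cw) / (H * W)
  q1 <- as.vector(softmaxRows(matrix(p1, 1L)))
  q2 <- as.vector(softmaxRows(matrix(p2, 1L)))
  X1m <- matrix(x1, H * W, cw)
  X2m <- matrix(x2, H * W, cw)
  msum <- as.vector(X2m %*% q1) + as.vector(X1m %*% q2)
  s <- sigmoid(msum) # (H*W), the bounded spatial modulation map
  y <- gx * s # recycled over channels
  list(y = y,
       cache = list(gx = gx, sh = sh, sw = sw, th = th, tw = tw,
                    x1pre = x1pre, m1 = m1, invstd = invstd, xhat = xhat,
                    x1 = x1, x2 = x2, q1 = q1, q2 = q2, s = s))
}

## Reverse-mode gradient for one group; returns dgx and parameter grads.
emaGroupBackward <- function(params, cache, dout) {
  gx <- cache$gx
  d <- dim(gx)
  H <- d[1L]; W <- d[2L]; cw <- d[3L]
  hw <- H * W
  s <- cache$s
  dgx <- dout * s
  ds <- .rowSums(matrix(dout * gx, hw, cw), hw, cw)
  dm <- ds * s * (1 - s)
  X1m <- matrix(cache$x1, hw, cw)
  X2m <- matrix(cache$x2, hw, cw)
  q1 <- cache$q1
  q2 <- cache$q2
  ## msum = X2m q1 + X1m q2
  dX2m <- outer(dm, q1)
  dq1 <- as.vector(crossprod(X2m, dm))
  dX1m <- outer(dm, q2)
  dq2 <- as.vector(crossprod(X1m, dm))
  ## softmax over channel descriptors
  dp1 <- q1 * (dq1 - sum(dq1 * q1))
  dp2 <- q2 * (dq2 - sum(dq2 * q2))
  dX1m <- dX1m + matrix(dp1 / hw, hw, cw, byrow = TRUE)
  dX2m <- dX2m + matrix(dp2 / hw, hw, cw, byrow = TRUE)
  ## 3x3 branch
  cv <- convBackward(array(gx, c(H, W, cw, 1L)), params$w3,
                     array(dX2m, c(H, W, cw, 1L)), needDx = TRUE)
  dgx <- dgx + array(cv$dx, d)
  ## instance-norm branch
  dx1 <- array(dX1m, d)
  dgamma <- .colSums(dx1 * cache$xhat, hw, cw)
  dbeta <- .colSums(dx1, hw, cw)
  dxhat <- dx1 * rep(params$gamma, each = hw)
  mh <- .colSums(dxhat, hw, cw) / hw
  mhx <- .colSums(dxhat * cache$xhat, hw, cw) / hw
  dpre <- rep(cache$invstd, each = hw) *
    (dxhat - rep(mh, each = hw) - cache$xhat * rep(mhx, each = hw))
  ## x1pre = gx * th * tw
  dgx <- dgx + dpre * cache$th * cache$tw
  dth <- dpre * gx * cache$tw
  dtw <- dpre * gx * cache$th
  dsh <- matrix(.colSums(aperm(dth, c(2L, 1L, 3L)), W, H * cw), H, cw)
  dsw <- matrix(.colSums(dtw, H, W * cw), W, cw)
  dzh <- dsh * cache$sh * (1 - cache$sh)
  dzw <- dsw * cache$sw * (1 - cache$sw)
  dz <- rbind(dzh, dzw)
  W1 <- matrix(params$w1, cw, cw)
  dp <- directionalPool(gx)
  dW1 <- crossprod(rbind(dp$row, dp$col), dz)
  db1 <- .colSums(dz, H + W, cw)
  dcat <- tcrossprod(dz, W1)
  drow <- dcat[seq_len(H), , drop = FALSE]
  dcol <- dcat[H + seq_len(W), , drop = FALSE]
  ## adjoints of the directional means
  dgx <- dgx + aperm(array(drow / W, c(H, cw, W)), c(1L, 3L, 2L)) +
    aperm(array(dcol / H, c(W, cw, H)), c(3L, 1L, 2L))
  list(dgx = dgx,
       grads = list(w1 = array(dW1, c(1L, 1L, cw, cw)), b1 = db1,
                    w3 = cv$dw, b3 = cv$db, gamma = dgamma, beta = dbeta))
}

## Batched EMA backward matching emaApply.
emaBackward <- function(params, cache, dy) {
  d <- cache$dim
  groups <- cache$groups
  cw <- d[3L] %/% groups
  dx <- array(0, d)
  grads <- NULL
  k <- 0L
  for (n in seq_len(d[4L])) {
    for (g in seq_len(groups)) {
      ch <- ((g - 1L) * cw + 1L):(g * cw)
      k <- k + 1L
      bg <- emaGroupBackward(params, cache$groupCaches[[k]],
                             array(dy[, , ch, n], c(d[1L], d[2L], cw)))
      dx[, , ch, n] <- bg$dgx
      grads <- if (is.null(grads)) bg$grads
               else mapply(`+`, grads, bg$grads, SIMPLIFY = FALSE)
    }
  }
  list(dx = dx, grads = grads)
}
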
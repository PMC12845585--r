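## Small internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

## Numerically safe softmax over the rows of a matrix.
softmaxRows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards (so generators are reproducible without
## clobbering global state).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Dense 1-D bilinear interpolation matrix (align-corners convention: the
## first/last samples of the input grid map exactly onto the first/last
## output positions; identity when nOut == nIn; constants are preserved).
bilinearMatrix <- function(nOut, nIn) {
  R <- matrix(0, nOut, nIn)
  if (nIn == 1L) {
    R[, 1L] <- 1
    return(R)
  }
  src <- if (nOut == 1L) 0 else (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
  i0 <- pmin(floor(src), nIn - 2)
  fr <- src - i0
  for (i in seq_len(nOut)) {
    R[i, i0[i] + 1L] <- 1 - fr[i]
    R[i, i0[i] + 2L] <- R[i, i0[i] + 2L] + fr[i]
  }
  R
}

## Promote a single (H,W,C) feature map to a 1-sample batch.
asBatch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

## Per-(channel, sample) sums of a (H,W,C,N) array -> (C,N) matrix,
## without any aperm: columns of the (HW x C*N) view are channel planes.
planeSums <- function(x) {
  d <- dim(x)
  matrix(.colSums(x, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L])
}

## Broadcast a per-(channel, sample) (C,N) matrix over the spatial dims of
## an (H,W,C,N) array (relies on column-major recycling: H,W vary fastest).
broadcastCN <- function(v, hw) rep(as.vector(v), each = hw)

isWholeNumber <- function(x) length(x) == 1L && is.finite(x) && x == round(x)
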
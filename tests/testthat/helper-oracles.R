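## Local bindings for internal package functions exercised by the suite.
sigmoid <- feswunet:::sigmoid
simamBackward <- feswunet:::simamBackward
emaInit <- feswunet:::emaInit
emaBackward <- feswunet:::emaBackward
emaParamCount <- feswunet:::emaParamCount
feamInit <- feswunet:::feamInit
feamBackward <- feswunet:::feamBackward
feamParamCount <- feswunet:::feamParamCount
feswForward <- feswunet:::feswForward
feswBackward <- feswunet:::feswBackward
hybridLoss <- feswunet:::hybridLoss
argmaxClasses <- feswunet:::argmaxClasses
stackSamples <- feswunet:::stackSamples
convForward <- feswunet:::convForward
hwdBackward <- feswunet:::hwdBackward
channelGateBackward <- feswunet:::channelGateBackward

## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths: brute-force optimisation, dense
## transform matrices and naive per-pixel loops.

## Brute-force minimiser of the canonical per-neuron energy: targets +1 for
## the neuron, -1 for the other M-1 neurons of the plane, ridge lambda w^2.
bruteForceEnergy <- function(plane, t, lambda) {
  others <- plane[-t]
  obj <- function(wb) {
    w <- wb[1]
    b <- wb[2]
    mean((-1 - (w * others + b))^2) + (1 - (w * plane[t] + b))^2 +
      lambda * w^2
  }
  optim(c(0, 0), obj, method = "BFGS",
        control = list(reltol = 1e-15, maxit = 500))$value
}

## Dense orthonormal Haar analysis matrix for a length-n signal (n even):
## first n/2 rows average pairs, last n/2 rows difference pairs, 1/sqrt(2).
haarMatrix1d <- function(n) {
  Hm <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    Hm[i, 2 * i - 1] <- 1 / sqrt(2)
    Hm[i, 2 * i] <- 1 / sqrt(2)
    Hm[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2)
    Hm[n / 2 + i, 2 * i] <- -1 / sqrt(2)
  }
  Hm
}

## Separable dense-matrix 2-D Haar decomposition of a single plane,
## returning the four subbands (rows transform = height axis).
haarDenseOracle <- function(p) {
  n <- nrow(p)
  m <- ncol(p)
  Hr <- haarMatrix1d(n)
  Hc <- haarMatrix1d(m)
  t2 <- Hr %*% p %*% t(Hc)
  lo_r <- seq_len(n / 2)
  hi_r <- n / 2 + lo_r
  lo_c <- seq_len(m / 2)
  hi_c <- m / 2 + lo_c
  list(A = t2[lo_r, lo_c], horiz = t2[lo_r, hi_c],
       vert = t2[hi_r, lo_c], diag = t2[hi_r, hi_c])
}

## Direct bilinear interpolation of a grid at one output position
## (align-corners), used as a closed-form projection oracle.
bilinearPointOracle <- function(grid, i, j, H, W) {
  src <- function(k, nOut, nIn) {
    if (nOut == 1 || nIn == 1) return(0)
    (k - 1) * (nIn - 1) / (nOut - 1)
  }
  si <- src(i, H, nrow(grid))
  sj <- src(j, W, ncol(grid))
  i0 <- min(floor(si), nrow(grid) - 2)
  j0 <- min(floor(sj), ncol(grid) - 2)
  fi <- si - i0
  fj <- sj - j0
  (1 - fi) * (1 - fj) * grid[i0 + 1, j0 + 1] +
    (1 - fi) * fj * grid[i0 + 1, j0 + 2] +
    fi * (1 - fj) * grid[i0 + 2, j0 + 1] +
    fi * fj * grid[i0 + 2, j0 + 2]
}

## Naive per-pixel confusion counts.
confusionLoopOracle <- function(pred, gt, K) {
  m <- matrix(0, K, K)
  for (i in seq_along(pred))
    m[gt[i] + 1, pred[i] + 1] <- m[gt[i] + 1, pred[i] + 1] + 1
  m
}

## Metric formulas recomputed directly from raw per-class counts.
metricFormulaOracle <- function(cm) {
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  iou <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 1)
  pa <- ifelse(tp + fn > 0, tp / (tp + fn), 1)
  f1 <- ifelse(tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 1)
  list(mIoU = mean(iou), mPA = mean(pa), accuracy = sum(tp) / sum(cm),
       mF1 = mean(f1))
}

## Small FEAM configs for 64x64-class inputs (scales must fit the skips).
smallFeamScales <- list(c(2L, 4L), c(4L, 8L))

randomFeature <- function(H, W, C, N = 1L, sd = 1) {
  array(rnorm(H * W * C * N, sd = sd), c(H, W, C, N))
}

asBatchLocal <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}
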
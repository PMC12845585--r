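#' Accumulate a pixel confusion matrix
#'
#' Adds the per-pixel cross-tabulation of reference against predicted
#' labels to the accumulator. Accumulation over batches is additive and
#' order-independent, and streaming updates equal a single update on the
#' concatenated masks.
#'
#' @param cm a [PixelConfusion-class].
#' @param pred,gt integer label arrays of identical shape with values in
#'   `0 .. nClasses - 1` (`gt` is the reference mask).
#' @return the updated [PixelConfusion-class].
#' @examples
#' cm <- pixelConfusion(2L)
#' cm <- confusionUpdate(cm, matrix(1L, 2, 2), matrix(1L, 2, 2))
#' @export
confusionUpdate <- function(cm, pred, gt) {
  stopIf(!is(cm, "PixelConfusion"), "'cm' must be a PixelConfusion")
  stopIf(!identical(dim(pred), dim(gt)) &&
           !(length(pred) == length(gt) && is.null(dim(pred)) ==
               is.null(dim(gt))),
         "'pred' and 'gt' must share a shape")
  K <- nrow(cm@counts)
  p <- as.vector(pred)
  g <- as.vector(gt)
  stopIf(any(p < 0L | p >= K | g < 0L | g >= K | p != round(p) |
               g != round(g)),
         "labels must be integers in 0..", K - 1L)
  idx <- g * K + p + 1L # row = reference class, column = prediction
  add <- matrix(tabulate(idx, nbins = K * K), K, K, byrow = TRUE)
  new("PixelConfusion", counts = cm@counts + add)
}

#' Per-class counts from a confusion accumulator
#'
#' @param cm a [PixelConfusion-class].
#' @return data frame with one row per class: `tp`, `fp`, `fn`, `tn`
#'   (their sum is the total pixel count for every class).
#' @export
confusionCounts <- function(cm) {
  m <- cm@counts
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- sum(m) - tp - fn - fp
  data.frame(class = seq_len(nrow(m)) - 1L, tp = tp, fp = fp, fn = fn,
             tn = tn, row.names = NULL)
}

#' Segmentation metrics from accumulated confusion counts
#'
#' Computes the macro-averaged metrics
#' \deqn{mIoU = \frac{1}{N}\sum_i \frac{TP_i}{TP_i + FP_i + FN_i}, \quad
#'       mPA = \frac{1}{N}\sum_i \frac{TP_i}{TP_i + FN_i},}
#' \deqn{mF1 = \frac{1}{N}\sum_i \frac{2\,TP_i}{2\,TP_i + FP_i + FN_i},}
#' and the pooled overall pixel accuracy \eqn{\sum_i TP_i / total}
#' (for the 4-way per-class decomposition this equals the trace of the
#' confusion matrix over the total pixel count). All values are fractions
#' in `[0, 1]`.
#'
#' A class absent from both prediction and reference (`TP + FP + FN = 0`)
#' contributes a vacuously perfect 1 under `absent = "perfect"` (default)
#' or is dropped from the macro averages under `absent = "skip"`.
#'
#' @param cm a [PixelConfusion-class] with at least one accumulated pixel.
#' @param absent zero-division rule for empty classes.
#' @return list with `mIoU`, `mPA`, `accuracy`, `mF1` and the per-class
#'   `iou`, `pa`, `f1` vectors.
#' @examples
#' cm <- confusionUpdate(pixelConfusion(2L),
#'                       pred = matrix(c(1L, 0L, 0L, 0L), 2),
#'                       gt = matrix(c(1L, 1L, 0L, 0L), 2))
#' computeMetrics(cm) # mIoU 7/12, mPA 0.75, accuracy 0.75, mF1 11/15
#' @export
computeMetrics <- function(cm, absent = c("perfect", "skip")) {
  absent <- match.arg(absent)
  stopIf(sum(cm@counts) == 0, "no pixels accumulated yet")
  cc <- confusionCounts(cm)
  denomIou <- cc$tp + cc$fp + cc$fn
  iou <- ifelse(denomIou > 0, cc$tp / denomIou, 1)
  pa <- ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), 1)
  f1 <- ifelse(denomIou > 0, 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn), 1)
  keep <- if (absent == "skip") denomIou > 0 else rep(TRUE, nrow(cc))
  list(mIoU = mean(iou[keep]), mPA = mean(pa[keep]),
       accuracy = sum(cc$tp) / sum(cm@counts), mF1 = mean(f1[keep]),
       iou = iou, pa = pa, f1 = f1)
}

#' Forward-pass throughput (frames per second)
#'
#' Times single-image forward passes of a model at a given square
#' resolution, excluding everything but the network forward itself (inputs
#' are pre-generated; no I/O, resizing or visualisation inside the timed
#' section). `warmup` untimed passes run first. FPS is the number of timed
#' images divided by the elapsed forward time; for one image it is the
#' reciprocal of the single-pass inference time. The result depends
#' entirely on the executing hardware.
#'
#' @param model a [FeswUNet-class].
#' @param nImages number of timed forward passes (>= 1; 50 or more for a
#'   stable figure).
#' @param resolution square input size; must be divisible by 16.
#' @param warmup untimed warm-up passes (default 10).
#' @param seed seed for the random timing inputs.
#' @return FPS as a single number, with attribute `"secondsPerImage"`.
#' @export
benchmarkFps <- function(model, nImages = 50L, resolution = 480L,
                         warmup = 10L, seed = 1L) {
  stopIf(nImages < 1L, "nImages must be >= 1")
  stopIf(resolution %% 16L != 0L,
         "resolution must be divisible by 16; got ", resolution)
  cin <- model@config@inChannels
  imgs <- withSeed(seed, lapply(seq_len(warmup + nImages), function(i)
    array(runif(resolution * resolution * cin),
          c(resolution, resolution, cin, 1L))))
  for (i in seq_len(warmup)) predictLogits(model, imgs[[i]])
  t0 <- proc.time()[["elapsed"]]
  for (i in warmup + seq_len(nImages)) predictLogits(model, imgs[[i]])
  el <- proc.time()[["elapsed"]] - t0
  structure(nImages / el, secondsPerImage = el / nImages)
}
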
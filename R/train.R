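#' Training configuration
#'
#' Optimisation settings for [trainModel()]. Defaults mirror the study
#' conditions (Adam, batch size 8, 100 epochs); the learning rate defaults
#' to `1e-4` (constant). `steps`, when given, caps the total number of
#' optimisation steps regardless of `epochs` (useful for smoke tests).
#'
#' @param batchSize images per optimisation step (>= 1).
#' @param epochs passes over the training set (>= 1).
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @param steps optional cap on total optimisation steps.
#' @param diceWeight weight of the Dice term in the hybrid loss
#'   (cross-entropy weight is fixed at 1; default equal weighting).
#' @param seed integer seed controlling shuffling (and any other training
#'   randomness).
#' @param logEvery record training loss every this many steps.
#' @param evalEvery evaluate training mIoU every this many epochs (the
#'   final state is always evaluated).
#' @param stopAtMiou optional early-stopping threshold: training ends as
#'   soon as an evaluated training mIoU exceeds this value.
#' @return a list of class `"trainConfig"`.
#' @export
trainConfig <- function(batchSize = 8L, epochs = 100L, lr = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        steps = NULL, diceWeight = 1, seed = 1L,
                        logEvery = 10L, evalEvery = 1L,
                        stopAtMiou = NULL) {
  stopIf(batchSize < 1L, "batchSize must be >= 1")
  stopIf(epochs < 1L, "epochs must be >= 1")
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps,
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 diceWeight = diceWeight, seed = as.integer(seed),
                 logEvery = as.integer(logEvery),
                 evalEvery = as.integer(evalEvery),
                 stopAtMiou = stopAtMiou),
            class = "trainConfig")
}

## Hybrid segmentation loss: pixel-wise cross-entropy plus soft Dice on the
## foreground class, equally weighted by default. Returns the scalar loss
## and its gradient w.r.t. the logits.
hybridLoss <- function(logits, masks, diceWeight = 1) {
  d <- dim(logits)
  hw <- d[1L] * d[2L]
  K <- d[3L]
  N <- d[4L]
  ## softmax over the class dimension
  zm <- matrix(aperm(logits, c(1L, 2L, 4L, 3L)), ncol = K)
  pm <- softmaxRows(zm)
  lab <- as.vector(masks) # (H,W,N) flattened matches rows of zm
  pick <- pm[cbind(seq_along(lab), lab + 1L)]
  ce <- -mean(log(pmax(pick, 1e-12)))
  npix <- length(lab)
  dce <- pm
  dce[cbind(seq_along(lab), lab + 1L)] <-
    dce[cbind(seq_along(lab), lab + 1L)] - 1
  dce <- dce / npix
  ## soft Dice on the foreground probability, pooled over the batch
  p1 <- pm[, 2L]
  y1 <- as.numeric(lab == 1L)
  inter <- sum(p1 * y1)
  tot <- sum(p1) + sum(y1)
  epsd <- 1e-6
  dice <- (2 * inter + epsd) / (tot + epsd)
  dloss_dp1 <- -(2 * y1 * (tot + epsd) - (2 * inter + epsd)) / (tot + epsd)^2
  ## chain through the softmax: dz_k = p_k (dp_k - sum_j dp_j p_j)
  dpm <- matrix(0, nrow(pm), K)
  dpm[, 2L] <- dloss_dp1 * diceWeight
  dz_dice <- pm * (dpm - rowSums(dpm * pm))
  dzm <- dce + dz_dice
  dlogits <- aperm(array(dzm, c(d[1L], d[2L], N, K)), c(1L, 2L, 4L, 3L))
  list(loss = ce + diceWeight * (1 - dice), ce = ce, dice = dice,
       dlogits = dlogits)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

## In-place fused Adam over the flat parameter list. The training loop
## deep-copies the parameters once up front, so exclusive ownership is
## guaranteed and the C++ kernel may update without reallocating.
adamStep <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads))
    cpp_adam(params[[nm]], state$m[[nm]], state$v[[nm]], grads[[nm]],
             lr, beta1, beta2, eps, bc1, bc2)
  list(params = params, state = state)
}

## Stack a list of segmentation samples into batch arrays.
stackSamples <- function(samples) {
  d <- dim(samples[[1L]]$image)
  n <- length(samples)
  x <- array(0, c(d[1L], d[2L], d[3L], n))
  y <- array(0L, c(d[1L], d[2L], n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train a FESW-UNet
#'
#' Full-gradient training with Adam and the hybrid cross-entropy + Dice
#' loss. Every source of randomness (shuffling) is driven by the seed in
#' `tc`, so identical inputs give identical runs. Per-logging-interval
#' training loss and per-epoch training mIoU are recorded.
#'
#' @param model a [FeswUNet-class] (from [buildModel()] or
#'   [loadCheckpoint()]).
#' @param samples list of segmentation samples (each a list with `image`
#'   `(H, W, C)` in `[0, 1]` and integer `mask` `(H, W)`); all must share
#'   one shape, spatial dims divisible by 16.
#' @param tc a [trainConfig()].
#' @param verbose print progress lines.
#' @return list with the trained `model`, a `history` data frame
#'   (`step`, `loss`, `ce`, `dice`) and `epochMiou` (training mIoU per
#'   completed epoch).
#' @export
trainModel <- function(model, samples, tc = trainConfig(), verbose = FALSE) {
  stopIf(length(samples) == 0L, "'samples' must be non-empty")
  cfg <- model@config
  p <- lapply(model@params, function(a) a + 0) # private copies (see adamStep)
  buf <- model@buffers
  st <- adamInit(p)
  history <- list()
  epochMiou <- numeric(0)
  step <- 0L
  maxSteps <- tc$steps %||% .Machine$integer.max
  done <- FALSE
  withSeed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample(length(samples))
      bs <- tc$batchSize
      nb <- ceiling(length(ord) / bs)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * bs + 1L):min(b * bs, length(ord))]
        batch <- stackSamples(samples[idx])
        fw <- feswForward(cfg, p, buf, batch$x, training = TRUE,
                          keepCache = TRUE)
        buf <- fw$buffers
        ls <- hybridLoss(fw$logits, batch$y, tc$diceWeight)
        grads <- feswBackward(cfg, p, fw$cache, ls$dlogits)
        upd <- adamStep(p, grads, st, tc$lr, tc$beta1, tc$beta2, tc$eps)
        p <- upd$params
        st <- upd$state
        step <- step + 1L
        if (step %% tc$logEvery == 0L || step == 1L) {
          history[[length(history) + 1L]] <-
            data.frame(step = step, loss = ls$loss, ce = ls$ce,
                       dice = ls$dice)
          if (verbose)
            message(sprintf("step %d: loss %.4f (ce %.4f, dice %.4f)",
                            step, ls$loss, ls$ce, ls$dice))
        }
        if (step >= maxSteps) {
          done <- TRUE
          break
        }
      }
      if (ep %% tc$evalEvery == 0L || done || ep == tc$epochs) {
        trained <- new("FeswUNet", config = cfg, params = p, buffers = buf)
        epochMiou <- c(epochMiou,
                       setNames(evaluateModel(trained, samples,
                                              batchSize = tc$batchSize)$mIoU,
                                ep))
        if (verbose)
          message(sprintf("epoch %d: train mIoU %.4f", ep,
                          epochMiou[length(epochMiou)]))
        if (!is.null(tc$stopAtMiou) &&
              epochMiou[length(epochMiou)] > tc$stopAtMiou)
          done <- TRUE
      }
      if (done) break
    }
  })
  list(model = new("FeswUNet", config = cfg, params = p, buffers = buf),
       history = do.call(rbind, history), epochMiou = epochMiou)
}

#' Evaluate a model on labelled samples
#'
#' Streams batches through the network in inference mode, accumulates a
#' pixel confusion matrix from the arg-max predictions and returns the
#' standard metric report. Streamed accumulation equals single-shot
#' computation on the concatenated masks.
#'
#' @param model a [FeswUNet-class].
#' @param samples list of segmentation samples (see [trainModel()]).
#' @param batchSize images per forward pass.
#' @param absent zero-division rule passed to [computeMetrics()].
#' @return metric list from [computeMetrics()].
#' @export
evaluateModel <- function(model, samples, batchSize = 8L,
                          absent = c("perfect", "skip")) {
  stopIf(length(samples) == 0L, "'samples' must be non-empty")
  K <- model@config@classes
  cm <- pixelConfusion(K)
  n <- length(samples)
  for (b in seq_len(ceiling(n / batchSize))) {
    idx <- ((b - 1L) * batchSize + 1L):min(b * batchSize, n)
    batch <- stackSamples(samples[idx])
    bad <- batch$y < 0L | batch$y >= K
    stopIf(any(bad), "mask labels outside 0..", K - 1L)
    logits <- predictLogits(model, batch$x)
    pred <- argmaxClasses(logits)
    cm <- confusionUpdate(cm, pred, batch$y)
  }
  computeMetrics(cm, absent = absent)
}

## Arg-max over the class dimension of (H, W, K, N) logits -> (H, W, N)
## integer labels in 0..K-1. Ties resolve to the lower class index.
argmaxClasses <- function(logits) {
  d <- dim(logits)
  zm <- matrix(aperm(logits, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  array(max.col(zm, ties.method = "first") - 1L, c(d[1L], d[2L], d[4L]))
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the full configuration together with all parameters
#' and buffers, so [loadCheckpoint()] reconstructs the exact model
#' (`modelConfig()` round-trips identically).
#'
#' @param model a [FeswUNet-class].
#' @param path file path (`.rds`).
#' @return `saveCheckpoint()` returns `path` invisibly; `loadCheckpoint()`
#'   returns the restored [FeswUNet-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "feswunet-checkpoint-v1",
               config = configAsList(model@config),
               params = model@params, buffers = model@buffers), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  stopIf(!identical(ck$format, "feswunet-checkpoint-v1"),
         "not a feswunet checkpoint: ", path)
  new("FeswUNet", config = do.call(feswConfig, ck$config),
      params = ck$params, buffers = ck$buffers)
}

configAsList <- function(cfg) {
  list(inChannels = cfg@inChannels, classes = cfg@classes,
       widths = cfg@widths, downsample = cfg@downsample,
       simam = cfg@simam, simamLambda = cfg@simamLambda, ema = cfg@ema,
       emaGroups = cfg@emaGroups, feamCount = cfg@feamCount,
       feamScales = cfg@feamScales,
       feamGateReduction = cfg@feamGateReduction, feamInit = cfg@feamInit,
       convBias = cfg@convBias, upBias = cfg@upBias, hwdBias = cfg@hwdBias)
}
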
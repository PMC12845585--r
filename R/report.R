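#' Count learnable parameters with a per-module breakdown
#'
#' Exact integer count of all learnable parameters of a built model,
#' decomposed by module (encoder, downsampling heads, bottleneck EMA, skip
#' FEAM blocks, decoder, classifier). SimAM contributes a zero row when
#' enabled: it is parameter-free by construction. The breakdown always sums
#' to the total; `millions` is the total divided by 1e6 rounded to 3
#' decimals (the convention used for reporting model sizes).
#'
#' @param model a [FeswUNet-class].
#' @return an object of class `"feswParamReport"`: a list with `total`,
#'   `millions` and a `breakdown` data frame (`module`, `parameters`).
#' @examples
#' m <- buildModel(feswConfig(downsample = "maxpool", simam = FALSE,
#'                            ema = FALSE, feamCount = 0L))
#' countParameters(m)
#' @export
countParameters <- function(model) {
  stopIf(!is(model, "FeswUNet"), "'model' must be a FeswUNet")
  p <- model@params
  n <- vapply(p, length, 1L)
  grp <- function(rx) sum(n[grepl(rx, names(n))])
  rows <- data.frame(
    module = c("encoder", "simam", "downsampling", "ema", "feam", "decoder",
               "classifier"),
    parameters = c(grp("^enc"), 0, grp("^down"), grp("^ema"), grp("^feam"),
                   grp("^up") + grp("^dec"), grp("^final")),
    stringsAsFactors = FALSE)
  keep <- rows$parameters > 0 | rows$module %in%
    c("encoder", "decoder", "classifier") |
    (rows$module == "simam" & model@config@simam)
  rows <- rows[keep, , drop = FALSE]
  total <- sum(n)
  stopifnot(sum(rows$parameters) == total)
  structure(list(total = total, millions = round(total / 1e6, 3L),
                 breakdown = rows),
            class = "feswParamReport")
}

#' @export
print.feswParamReport <- function(x, ...) {
  cat(sprintf("Learnable parameters: %s (%.3f M)\n",
              format(x$total, big.mark = ","), x$millions))
  for (i in seq_len(nrow(x$breakdown)))
    cat(sprintf("  %-13s %12s\n", x$breakdown$module[i],
                format(x$breakdown$parameters[i], big.mark = ",")))
  invisible(x)
}

#' Run the network forward and return class logits
#'
#' Deterministic inference-mode forward pass (batch-norm running
#' statistics, no dropout-like stochasticity anywhere in the
#' architecture). Input spatial dimensions must be divisible by 16.
#'
#' @param model a [FeswUNet-class].
#' @param x image array `(H, W, C)` or batch `(H, W, C, N)` with `C`
#'   matching the configured input channels, values typically in `[0, 1]`.
#' @return logits array `(H, W, classes)` (or batched), same spatial size
#'   as the input.
#' @export
predictLogits <- function(model, x) {
  x3 <- length(dim(x)) == 3L
  out <- feswForward(model@config, model@params, model@buffers, asBatch(x),
                     training = FALSE, keepCache = FALSE)
  y <- out$logits
  if (x3) dim(y) <- dim(y)[1:3]
  y
}

#' Standard ablation configurations
#'
#' The ten backbone variants used in the block-wise ablation: every
#' combination of EMA, SimAM, HWD and FEAM(x2) that the study reports, from
#' the plain U-Net baseline to the full FESW-UNet. All share the canonical
#' widths 64-1024 and two output classes.
#'
#' @return named list of [FeswConfig-class] objects.
#' @export
ablationConfigs <- function() {
  base <- function(...) {
    args <- modifyList(list(downsample = "maxpool", simam = FALSE,
                            ema = FALSE, feamCount = 0L), list(...))
    do.call(feswConfig, args)
  }
  list(
    unet = base(),
    `+ema` = base(ema = TRUE),
    `+simam` = base(simam = TRUE),
    `+hwd` = base(downsample = "hwd"),
    `+feam` = base(feamCount = 2L),
    `+ema+simam` = base(ema = TRUE, simam = TRUE),
    `+ema+hwd+feam` = base(ema = TRUE, downsample = "hwd", feamCount = 2L),
    `+ema+simam+feam` = base(ema = TRUE, simam = TRUE, feamCount = 2L),
    `+ema+simam+hwd` = base(ema = TRUE, simam = TRUE, downsample = "hwd"),
    fesw = feswConfig())
}

#' Published reference results
#'
#' Reported evaluation results of FESW-UNet and the baseline U-Net on the
#' two field datasets (Aphid Cluster Segmentation; AphidSeg-Sorghum), as
#' percentages. These figures come from GPU-scale training on the external
#' datasets; they are reference targets for users who hold the data, not
#' quantities this package recomputes (inference-speed figures are
#' hardware-specific and deliberately excluded).
#'
#' @return data frame with columns `dataset`, `model`, `mIoU`, `mPA`,
#'   `accuracy`, `mF1`, `paramsM`.
#' @export
publishedBenchmarks <- function() {
  data.frame(
    dataset = rep(c("AphidClusterSegmentation", "AphidSegSorghum"), each = 2),
    model = rep(c("UNet", "FESW-UNet"), 2),
    mIoU = c(66.31, 68.76, 71.43, 81.22),
    mPA = c(75.79, 78.19, 77.42, 87.97),
    accuracy = c(92.65, 93.32, 98.04, 98.75),
    mF1 = c(76.74, 79.01, 80.64, 88.60),
    paramsM = c(31.031, 32.756, 31.031, 32.756),
    stringsAsFactors = FALSE)
}
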
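#' Model configuration for FESW-UNet
#'
#' Declarative description of the encoder-decoder and its optional blocks.
#' The backbone is the canonical U-Net: five double-convolution stages with
#' widths doubling from `widths[1]` to `widths[5]`, four downsampling
#' steps, transposed-convolution upsampling and a final 1x1 classifier.
#' Convolutions followed by batch normalisation carry no bias by default;
#' transposed convolutions and the HWD head do. Any subset of the four
#' blocks can be enabled independently.
#'
#' @slot inChannels integer, input image channels (3 for RGB).
#' @slot classes integer, output classes (2: background, aphid).
#' @slot widths integer vector of 5 encoder stage widths (each double the
#'   previous).
#' @slot downsample `"maxpool"` or `"hwd"` (Haar-wavelet downsampling).
#' @slot simam logical, insert parameter-free SimAM attention after every
#'   encoder stage.
#' @slot simamLambda positive energy regularisation (default `1e-4`).
#' @slot ema logical, insert the EMA block at the bottleneck.
#' @slot emaGroups channel groups for EMA (must divide the bottleneck
#'   width; default 8).
#' @slot feamCount number of FEAM blocks (0--4), attached to the skip
#'   connections from the deepest outwards.
#' @slot feamScales list of per-block nominal scale pairs (defaults
#'   `[30,60], [60,120], [120,240], [240,480]`, deepest skip first).
#' @slot feamGateReduction bottleneck reduction of the FEAM channel gate.
#' @slot feamInit `"identity"` (alpha 1, beta 0) or `"random"`.
#' @slot convBias logical, bias on convolutions that precede batch norm.
#' @slot upBias logical, bias on transposed convolutions.
#' @slot hwdBias logical, bias on the HWD 1x1 head.
#' @seealso [feswConfig()], [buildModel()]
#' @export
setClass("FeswConfig",
  representation(inChannels = "integer", classes = "integer",
                 widths = "integer", downsample = "character",
                 simam = "logical", simamLambda = "numeric",
                 ema = "logical", emaGroups = "integer",
                 feamCount = "integer", feamScales = "list",
                 feamGateReduction = "integer", feamInit = "character",
                 convBias = "logical", upBias = "logical",
                 hwdBias = "logical"))

setValidity("FeswConfig", function(object) {
  w <- object@widths
  if (length(w) != 5L) return("exactly 5 encoder widths are required")
  if (any(w[-1L] != 2L * w[-5L])) return("widths must double per stage")
  if (!object@downsample %in% c("maxpool", "hwd"))
    return("downsample must be 'maxpool' or 'hwd'")
  if (object@ema && w[5L] %% object@emaGroups != 0L)
    return(sprintf("bottleneck width %d not divisible by emaGroups %d",
                   w[5L], object@emaGroups))
  if (object@feamCount < 0L || object@feamCount > 4L)
    return("feamCount must be between 0 and 4")
  if (object@feamCount > length(object@feamScales))
    return("feamScales must provide a scale pair for every FEAM block")
  if (object@simamLambda <= 0) return("simamLambda must be positive")
  if (!object@feamInit %in% c("identity", "random"))
    return("feamInit must be 'identity' or 'random'")
  TRUE
})

#' Construct a model configuration
#'
#' @param inChannels,classes input channels and output classes.
#' @param widths five encoder stage widths, doubling per stage.
#' @param downsample `"maxpool"` (classical U-Net) or `"hwd"`.
#' @param simam,simamLambda enable SimAM; its energy regularisation.
#' @param ema,emaGroups enable bottleneck EMA; its channel-group count.
#' @param feamCount number of FEAM skip blocks (0--4), deepest first.
#' @param feamScales list of nominal scale pairs per block.
#' @param feamGateReduction channel-gate bottleneck reduction.
#' @param feamInit spectral weight initialisation.
#' @param convBias,upBias,hwdBias bias conventions (see [FeswConfig-class]).
#' @return a validated [FeswConfig-class] object. The default arguments
#'   describe the full FESW-UNet (SimAM + EMA + HWD + FEAM x 2).
#' @examples
#' cfg <- feswConfig(downsample = "maxpool", simam = FALSE, ema = FALSE,
#'                   feamCount = 0L) # baseline U-Net
#' @export
feswConfig <- function(inChannels = 3L, classes = 2L,
                       widths = c(64L, 128L, 256L, 512L, 1024L),
                       downsample = "hwd",
                       simam = TRUE, simamLambda = 1e-4,
                       ema = TRUE, emaGroups = 8L,
                       feamCount = 2L,
                       feamScales = list(c(30L, 60L), c(60L, 120L),
                                         c(120L, 240L), c(240L, 480L)),
                       feamGateReduction = 4L, feamInit = "identity",
                       convBias = FALSE, upBias = TRUE, hwdBias = TRUE) {
  new("FeswConfig", inChannels = as.integer(inChannels),
      classes = as.integer(classes), widths = as.integer(widths),
      downsample = downsample, simam = isTRUE(simam),
      simamLambda = as.numeric(simamLambda), ema = isTRUE(ema),
      emaGroups = as.integer(emaGroups), feamCount = as.integer(feamCount),
      feamScales = lapply(feamScales, as.integer),
      feamGateReduction = as.integer(feamGateReduction),
      feamInit = feamInit, convBias = isTRUE(convBias),
      upBias = isTRUE(upBias), hwdBias = isTRUE(hwdBias))
}

#' The FESW-UNet model object
#'
#' Holds the configuration, all learnable parameters (a flat named list of
#' numeric arrays) and the non-learnable buffers (batch-norm running
#' statistics). Created by [buildModel()]; use [nParameters()],
#' [modelConfig()] and [countParameters()] to inspect it, and
#' [predictLogits()] / [trainModel()] to run it.
#'
#' @slot config a [FeswConfig-class].
#' @slot params named list of numeric arrays (learnable parameters).
#' @slot buffers named list of running statistics.
#' @export
setClass("FeswUNet",
  representation(config = "FeswConfig", params = "list", buffers = "list"))

#' Accumulating pixel-level confusion matrix
#'
#' Square count matrix with reference (ground-truth) classes in rows and
#' predicted classes in columns, accumulated over batches with
#' [confusionUpdate()]; accumulation is additive and order-independent.
#' Backs all segmentation metrics ([computeMetrics()]).
#'
#' @slot counts numeric `N x N` matrix of pixel counts.
#' @export
setClass("PixelConfusion", representation(counts = "matrix"))

setValidity("PixelConfusion", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (any(cm < 0)) return("counts must be non-negative")
  if (any(cm != round(cm))) return("counts must be whole numbers")
  TRUE
})

#' Create an empty pixel confusion accumulator
#' @param nClasses number of label classes (default 2).
#' @return a [PixelConfusion-class] with zero counts.
#' @export
pixelConfusion <- function(nClasses = 2L) {
  new("PixelConfusion", counts = matrix(0, nClasses, nClasses))
}

#' Number of learnable parameters
#' @param object a [FeswUNet-class] model.
#' @return integer-valued numeric count.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "FeswUNet", function(object)
  sum(vapply(object@params, length, 1L)))

#' Configuration of a built model
#' @param object a [FeswUNet-class] model.
#' @return the [FeswConfig-class] the model was built from.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "FeswUNet", function(object) object@config)

setMethod("show", "FeswConfig", function(object) {
  blocks <- c(if (object@simam) "SimAM",
              if (object@ema) sprintf("EMA(g=%d)", object@emaGroups),
              if (object@downsample == "hwd") "HWD",
              if (object@feamCount > 0L)
                sprintf("FEAM x %d", object@feamCount))
  cat(sprintf("FeswConfig: %d -> %d classes, widths %s, %s downsampling\n",
              object@inChannels, object@classes,
              paste(object@widths, collapse = "-"), object@downsample))
  cat("  blocks:", if (length(blocks)) paste(blocks, collapse = " + ")
                   else "none (baseline U-Net)", "\n")
})

setMethod("show", "FeswUNet", function(object) {
  cat("FESW-UNet model\n")
  show(object@config)
  cat(sprintf("  parameters: %s (%.3f M)\n",
              format(nParameters(object), big.mark = ","),
              nParameters(object) / 1e6))
})

setMethod("show", "PixelConfusion", function(object) {
  cat(sprintf("PixelConfusion over %d classes, %s pixels\n",
              nrow(object@counts),
              format(sum(object@counts), big.mark = ",")))
  print(object@counts)
})
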
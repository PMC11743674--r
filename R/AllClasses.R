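#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib msgunet, .registration = TRUE
NULL

#' Network configuration
#'
#' Geometry of the segmentation networks: the five encoder stage widths
#' C1..C5, the input/output channel counts and the nominal square input size.
#' Stage widths must be divisible by 16 (the SPP-Inception quarter-channel
#' split and the 16-group normalisation inside ELA both require it) and the
#' input size divisible by 16 (four 2x2 poolings).
#'
#' @slot stageChannels integer(5), encoder widths C1..C5.
#' @slot inChannels integer(1), input image channels (3 for RGB).
#' @slot outChannels integer(1), logit channels (1 for binary masks).
#' @slot inputSize integer(1), nominal square input size in pixels.
#' @export
setClass("NetworkConfig",
  representation(stageChannels = "numeric", inChannels = "numeric",
                 outChannels = "numeric", inputSize = "numeric"),
  prototype(stageChannels = c(32, 64, 128, 256, 512),
            inChannels = 3, outChannels = 1, inputSize = 256))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@stageChannels) != 5L)
    msg <- c(msg, "stageChannels must have length 5")
  if (any(object@stageChannels %% 16 != 0) || any(object@stageChannels < 16))
    msg <- c(msg, "every stage channel must be a positive multiple of 16")
  if (object@inChannels < 1 || object@outChannels < 1)
    msg <- c(msg, "inChannels and outChannels must be >= 1")
  if (object@inputSize %% 16 != 0 || object@inputSize < 16)
    msg <- c(msg, "inputSize must be a positive multiple of 16")
  if (length(msg)) msg else TRUE
})

#' Create a network configuration
#'
#' @param stageChannels encoder stage widths C1..C5; default
#'   \code{c(32, 64, 128, 256, 512)}.
#' @param inChannels input channels (3 = RGB).
#' @param outChannels output logit channels (1 = binary).
#' @param inputSize nominal square input size in pixels, divisible by 16.
#' @return A \linkS4class{NetworkConfig}.
#' @examples
#' networkConfig()
#' @export
networkConfig <- function(stageChannels = c(32, 64, 128, 256, 512),
                          inChannels = 3, outChannels = 1, inputSize = 256) {
  new("NetworkConfig", stageChannels = as.numeric(stageChannels),
      inChannels = as.numeric(inChannels),
      outChannels = as.numeric(outChannels),
      inputSize = as.numeric(inputSize))
}

#' Segmentation network instance
#'
#' A built network: the architecture description (an ordered list of layer
#' descriptors that drives weight initialisation, the forward pass and the
#' profiler), the trainable parameters and the normalisation buffers.
#' Parameters and buffers live in environments, so a network is modified in
#' place by training (reference semantics, like an external pointer).
#'
#' @slot kind "msgunet" or "unet".
#' @slot config the \linkS4class{NetworkConfig} used to build the network.
#' @slot arch ordered list of layer descriptors.
#' @slot params environment mapping parameter names to numeric arrays.
#' @slot buffers environment holding batch-norm running moments.
#' @slot seed integer seed the weights were initialised from.
#' @export
setClass("SegNetwork",
  representation(kind = "character", config = "NetworkConfig", arch = "list",
                 params = "environment", buffers = "environment",
                 seed = "numeric"))

#' Architecture cost report
#'
#' Trainable-parameter and multiply-accumulate (MAC) counts for one forward
#' pass of a single image.  The GFLOPs figure follows the comparison
#' literature's convention of one "FLOP" per multiply-accumulate; pooling,
#' up-sampling, normalisation and element-wise gates are counted as zero.
#'
#' @slot totalParams total trainable scalars.
#' @slot totalMACs total multiply-accumulates for one image.
#' @slot perModule data.frame with columns module, params, macs.
#' @slot geometry input geometry c(channels, height, width).
#' @export
setClass("ProfileReport",
  representation(totalParams = "numeric", totalMACs = "numeric",
                 perModule = "data.frame", geometry = "numeric"))

setValidity("ProfileReport", function(object) {
  ok_p <- object@totalParams == sum(object@perModule$params)
  ok_m <- object@totalMACs == sum(object@perModule$macs)
  if (ok_p && ok_m) TRUE else "per-module sums do not reconcile with totals"
})

#' Segmentation metrics report
#'
#' Confusion counts pooled over all evaluated pixels plus per-image metrics.
#' Headline figures are per-image means: \code{dsc} the Dice-Sorensen
#' coefficient, \code{miou} the foreground IoU (the convention used in the
#' lightweight-segmentation comparison literature), \code{miouTwoClass} the
#' two-class (foreground/background) mean IoU, and pixel accuracy,
#' sensitivity and specificity.
#'
#' @slot counts named numeric: pooled tp, fp, tn, fn pixel counts.
#' @slot perImage data.frame of per-image counts and metrics.
#' @slot dsc,miou,miouTwoClass,acc,sen,spe per-image mean metrics.
#' @slot threshold probability threshold used for binarisation.
#' @export
setClass("MetricsReport",
  representation(counts = "numeric", perImage = "data.frame",
                 dsc = "numeric", miou = "numeric", miouTwoClass = "numeric",
                 acc = "numeric", sen = "numeric", spe = "numeric",
                 threshold = "numeric"))

#' Synthetic dermoscopy generator configuration
#'
#' Parameters of the seeded synthetic dermoscopy image generator: skin-toned
#' backgrounds with one darker, irregular elliptical lesion per image,
#' optional dark hair strands occluding the image (never the mask), and
#' Gaussian pixel noise.
#'
#' @slot nSamples number of image/mask pairs.
#' @slot imageSize square image size in pixels.
#' @slot lesionAreaRange fraction interval for the lesion area, inside (0, 0.9).
#' @slot hairProbability probability a sample receives hair strands.
#' @slot noiseSd Gaussian noise standard deviation on the [0, 1] intensity scale.
#' @slot seed integer seed; the full dataset is reproducible from it.
#' @export
setClass("SynthConfig",
  representation(nSamples = "numeric", imageSize = "numeric",
                 lesionAreaRange = "numeric", hairProbability = "numeric",
                 noiseSd = "numeric", seed = "numeric"),
  prototype(nSamples = 16, imageSize = 256, lesionAreaRange = c(0.05, 0.45),
            hairProbability = 0.3, noiseSd = 0.02, seed = 1))

setValidity("SynthConfig", function(object) {
  msg <- character()
  r <- object@lesionAreaRange
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 0.9 || r[1] >= r[2])
    msg <- c(msg, "lesionAreaRange must be an increasing interval inside (0, 0.9)")
  if (object@nSamples < 1) msg <- c(msg, "nSamples must be >= 1")
  if (object@imageSize < 16) msg <- c(msg, "imageSize must be >= 16")
  if (object@hairProbability < 0 || object@hairProbability > 1)
    msg <- c(msg, "hairProbability must be in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-data configuration
#'
#' @param nSamples number of image/mask pairs to generate.
#' @param imageSize square image size in pixels.
#' @param lesionAreaRange interval of admissible lesion area fractions.
#' @param hairProbability probability of hair-strand occluders per sample.
#' @param noiseSd Gaussian pixel noise sd on the [0, 1] scale.
#' @param seed integer seed.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' synthConfig(nSamples = 4, imageSize = 64, seed = 7)
#' @export
synthConfig <- function(nSamples = 16, imageSize = 256,
                        lesionAreaRange = c(0.05, 0.45),
                        hairProbability = 0.3, noiseSd = 0.02, seed = 1) {
  new("SynthConfig", nSamples = as.numeric(nSamples),
      imageSize = as.numeric(imageSize),
      lesionAreaRange = as.numeric(lesionAreaRange),
      hairProbability = as.numeric(hairProbability),
      noiseSd = as.numeric(noiseSd), seed = as.numeric(seed))
}
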
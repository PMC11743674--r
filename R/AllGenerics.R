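#' Count trainable parameters
#'
#' Enumerates every trainable array of a built network (convolution kernels,
#' biases, normalisation scales and shifts) and returns the total number of
#' scalars.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @return integer-valued numeric scalar.
#' @export
setGeneric("countParams", function(net) standardGeneric("countParams"))

#' Count multiply-accumulate operations
#'
#' Multiply-accumulate (MAC) count of one forward pass on a single image of
#' the given size: for every convolution,
#' \code{out_h * out_w * out_c * (in_c / groups) * k_h * k_w}.  Pooling,
#' up-sampling, normalisation and element-wise gates are counted as zero,
#' the convention of the lightweight-segmentation comparison literature.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param inputSize square input size in pixels (divisible by 16); defaults
#'   to the network's configured input size.
#' @return numeric MAC count (divide by 1e9 for the GFLOPs figure).
#' @export
setGeneric("countMACs", function(net, inputSize) standardGeneric("countMACs"))

#' Profile a network
#'
#' Per-module and total trainable-parameter and MAC counts.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param inputSize square input size in pixels; defaults to the configured
#'   input size.
#' @return A \linkS4class{ProfileReport}.
#' @export
setGeneric("profileNetwork",
           function(net, inputSize) standardGeneric("profileNetwork"))

#' Run a forward pass
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param x input batch, an (H, W, C, N) array with C equal to the configured
#'   input channels and H, W divisible by 16.
#' @param mode "eval" (running batch-norm moments; deterministic) or "train"
#'   (batch statistics).
#' @return logits as an (H, W, outChannels, N) array (no activation; the loss
#'   and the evaluator apply the sigmoid).
#' @export
setGeneric("netForward", function(net, x, mode = "eval")
  standardGeneric("netForward"))

#' @rdname NetworkConfig-class
#' @param object,x a NetworkConfig.
#' @export
setGeneric("stageChannels", function(x) standardGeneric("stageChannels"))

#' @rdname NetworkConfig-class
#' @export
setGeneric("inputSize", function(x) standardGeneric("inputSize"))

#' @rdname ProfileReport-class
#' @param x a ProfileReport.
#' @export
setGeneric("totalParams", function(x) standardGeneric("totalParams"))

#' @rdname ProfileReport-class
#' @export
setGeneric("totalMACs", function(x) standardGeneric("totalMACs"))

#' @rdname ProfileReport-class
#' @export
setGeneric("perModule", function(x) standardGeneric("perModule"))

#' Extract the headline metrics of a report as a named vector
#'
#' @param x a \linkS4class{MetricsReport}.
#' @return named numeric vector with dsc, miou, miouTwoClass, acc, sen, spe.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

setMethod("stageChannels", "NetworkConfig", function(x) x@stageChannels)
setMethod("inputSize", "NetworkConfig", function(x) x@inputSize)
setMethod("totalParams", "ProfileReport", function(x) x@totalParams)
setMethod("totalMACs", "ProfileReport", function(x) x@totalMACs)
setMethod("perModule", "ProfileReport", function(x) x@perModule)
setMethod("metricValues", "MetricsReport", function(x)
  c(dsc = x@dsc, miou = x@miou, miouTwoClass = x@miouTwoClass,
    acc = x@acc, sen = x@sen, spe = x@spe))

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig: stages", paste(object@stageChannels, collapse = "/"),
      "| in", object@inChannels, "out", object@outChannels,
      "| input", paste0(object@inputSize, "x", object@inputSize), "\n")
})

setMethod("show", "SegNetwork", function(object) {
  cat(sprintf("SegNetwork <%s>: %s trainable parameters (seed %d)\n",
              object@kind, format(countParams(object), big.mark = ","),
              as.integer(object@seed)))
  show(object@config)
})

setMethod("show", "ProfileReport", function(object) {
  cat(sprintf(
    "ProfileReport at input %dx%dx%d\n  params: %s (%.4f M)\n  MACs:   %s (%.4f G, 1 FLOP per MAC)\n",
    object@geometry[1], object@geometry[2], object@geometry[3],
    format(object@totalParams, big.mark = ","), object@totalParams / 1e6,
    format(object@totalMACs, big.mark = ",", scientific = FALSE),
    object@totalMACs / 1e9))
  cat("  modules:", nrow(object@perModule), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  v <- metricValues(object)
  cat(sprintf(
    "MetricsReport (%d images, threshold %.2f)\n  DSC %.4f | mIoU(fg) %.4f | mIoU(2-class) %.4f\n  Acc %.4f | Sen %.4f | Spe %.4f\n",
    nrow(object@perImage), object@threshold,
    v["dsc"], v["miou"], v["miouTwoClass"], v["acc"], v["sen"], v["spe"]))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d samples of %dx%d px | lesion area in [%.2f, %.2f] | hair p=%.2f | noise sd %.3f | seed %d\n",
    object@nSamples, object@imageSize, object@imageSize,
    object@lesionAreaRange[1], object@lesionAreaRange[2],
    object@hairProbability, object@noiseSd, as.integer(object@seed)))
})
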
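# Architecture cost accounting.
#
# Parameters are counted two ways on purpose: countParams() enumerates the
# actual weight arrays of a built network, while profileNetwork() derives the
# count per layer from the architecture descriptors.  The two must agree to
# the last integer (a unit test holds them together).
#
# MAC counting follows the comparison-literature convention: for every
# convolution out_h * out_w * out_c * (in_c / groups) * k_h * k_w; pooling,
# bilinear up-sampling, normalisation and element-wise gates cost zero.
# "GFLOPs" figures are MACs / 1e9 (one FLOP per multiply-accumulate).

#' @rdname countParams
#' @export
setMethod("countParams", "SegNetwork", function(net) {
  nms <- ls(net@params, all.names = TRUE)
  sum(vapply(nms, function(nm)
    length(get(nm, envir = net@params, inherits = FALSE)), numeric(1)))
})

layer_params <- function(ly) {
  if (ly$kind == "gn") return(2 * ly$channels)
  p <- as.numeric(ly$kh) * ly$kw * (ly$cin %/% ly$groups) * ly$cout
  if (ly$bias) p <- p + ly$cout
  if (ly$bn) p <- p + 2 * ly$cout
  p
}

layer_macs <- function(ly, inputSize) {
  if (ly$kind == "gn") return(0)
  s <- inputSize %/% ly$div
  if (isTRUE(ly$dfc)) s <- s %/% 2          # DFC branch runs at half resolution
  dims <- switch(ly$spatial,
                 "2d" = c(s, s),
                 "striph" = c(s, 1),
                 "stripw" = c(s, 1),
                 stop("unknown spatial kind"))
  as.numeric(dims[1]) * dims[2] * ly$cout * (ly$cin %/% ly$groups) *
    ly$kh * ly$kw
}

#' @rdname countMACs
#' @export
setMethod("countMACs", "SegNetwork", function(net, inputSize) {
  if (missing(inputSize)) inputSize <- net@config@inputSize
  if (inputSize %% 16 != 0) stop("inputSize must be divisible by 16")
  sum(vapply(net@arch$layers, layer_macs, numeric(1),
             inputSize = inputSize))
})

#' @rdname profileNetwork
#' @export
setMethod("profileNetwork", "SegNetwork", function(net, inputSize) {
  if (missing(inputSize)) inputSize <- net@config@inputSize
  if (inputSize %% 16 != 0) stop("inputSize must be divisible by 16")
  tab <- data.frame(
    module = vapply(net@arch$layers, `[[`, "", "name"),
    params = vapply(net@arch$layers, layer_params, numeric(1)),
    macs = vapply(net@arch$layers, layer_macs, numeric(1),
                  inputSize = inputSize),
    stringsAsFactors = FALSE)
  new("ProfileReport", totalParams = sum(tab$params), totalMACs = sum(tab$macs),
      perModule = tab,
      geometry = c(net@config@inChannels, inputSize, inputSize))
})

#' Cost reduction relative to a baseline
#'
#' Percentage reductions \code{(1 - ours / baseline) * 100} in trainable
#' parameters and MACs, comparing two profiles taken at the same input
#' geometry.
#'
#' @param ours \linkS4class{ProfileReport} of the lightweight network.
#' @param baseline \linkS4class{ProfileReport} of the reference network.
#' @return named numeric vector with \code{params} and \code{macs}
#'   reductions, in percent.
#' @examples
#' \donttest{
#' r <- reductionReport(profileNetwork(buildMSGUNet()),
#'                      profileNetwork(buildUNetBaseline()))
#' }
#' @export
reductionReport <- function(ours, baseline) {
  stopifnot(is(ours, "ProfileReport"), is(baseline, "ProfileReport"))
  if (!identical(ours@geometry[2:3], baseline@geometry[2:3]))
    stop("profiles were taken at different input geometries")
  if (baseline@totalParams == 0 || baseline@totalMACs == 0)
    stop("baseline has zero cost")
  c(params = (1 - ours@totalParams / baseline@totalParams) * 100,
    macs = (1 - ours@totalMACs / baseline@totalMACs) * 100)
}
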
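# Network assembly: MSGU-Net and the plain U-Net baseline.
#
# MSGU-Net encoder stages 1-4 run SPP-Inception (prev -> C_i), a Ghost module
# with DFC attention (C_i -> C_i) and ELA, then 2x2 max pooling; the
# bottleneck (stage 5) runs Ghost (C4 -> C5) and ELA only.  Each decoder step
# bilinearly up-samples 2x, gates the skip with the up-sampled feature as the
# gating signal, concatenates, and maps back to C_i with a Ghost module.
# A 1x1 head emits logits (the loss and the evaluator apply the sigmoid).

arch_msgunet <- function(config, useEla = TRUE, useDfc = TRUE) {
  ch <- config@stageChannels
  layers <- list()
  prev <- config@inChannels
  for (i in 1:5) {
    div <- 2^(i - 1)
    if (i < 5) {
      layers <- c(layers,
                  spp_layers(sprintf("enc%d.spp", i), prev, ch[i], div),
                  ghost_layers(sprintf("enc%d.ghost", i), ch[i], ch[i], div,
                               dfc = useDfc))
    } else {
      layers <- c(layers,
                  ghost_layers(sprintf("enc%d.ghost", i), prev, ch[i], div,
                               dfc = useDfc))
    }
    if (useEla)
      layers <- c(layers, ela_layers(sprintf("enc%d.ela", i), ch[i], div))
    prev <- ch[i]
  }
  for (i in 4:1) {
    div <- 2^(i - 1)
    layers <- c(layers,
                gate_layers(sprintf("dec%d.gate", i), ch[i], ch[i + 1],
                            max(1L, ch[i] %/% 4L), div),
                ghost_layers(sprintf("dec%d.ghost", i), ch[i] + ch[i + 1],
                             ch[i], div, dfc = useDfc))
  }
  layers <- c(layers, list(
    conv_layer("head", ch[1], config@outChannels, 1, 1, c(0, 0), bias = TRUE,
               bn = FALSE, act = "none", div = 1L)))
  list(layers = layers, opts = list(useEla = useEla, useDfc = useDfc))
}

arch_unet <- function(config) {
  ch <- config@stageChannels
  layers <- list()
  prev <- config@inChannels
  for (i in 1:5) {
    div <- 2^(i - 1)
    layers <- c(layers, list(
      conv_layer(sprintf("enc%d.c1", i), prev, ch[i], 3, 3, c(1, 1), div = div),
      conv_layer(sprintf("enc%d.c2", i), ch[i], ch[i], 3, 3, c(1, 1),
                 div = div)))
    prev <- ch[i]
  }
  for (i in 4:1) {
    div <- 2^(i - 1)
    layers <- c(layers, list(
      conv_layer(sprintf("dec%d.c1", i), ch[i] + ch[i + 1], ch[i], 3, 3,
                 c(1, 1), div = div),
      conv_layer(sprintf("dec%d.c2", i), ch[i], ch[i], 3, 3, c(1, 1),
                 div = div)))
  }
  layers <- c(layers, list(
    conv_layer("head", ch[1], config@outChannels, 1, 1, c(0, 0), bias = TRUE,
               bn = FALSE, act = "none", div = 1L)))
  list(layers = layers, opts = list())
}

new_network <- function(kind, config, arch, seed) {
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  with_seed(seed, init_layers(arch$layers, params, buffers))
  new("SegNetwork", kind = kind, config = config, arch = arch,
      params = params, buffers = buffers, seed = as.numeric(seed))
}

#' Build MSGU-Net
#'
#' Assembles the lightweight multi-scale Ghost U-Net: five encoder stages
#' (SPP-Inception + Ghost/DFC + ELA for stages 1-4, Ghost/DFC + ELA at the
#' bottleneck), four attention-gated decoder stages with bilinear
#' up-sampling, and a 1x1 logit head.  Weight initialisation is He-normal
#' and fully determined by \code{seed}.
#'
#' @param config a \linkS4class{NetworkConfig}; the default reproduces the
#'   reference geometry (stages 32/64/128/256/512, RGB in, one logit out).
#' @param seed integer initialisation seed.
#' @param useEla include the ELA attention blocks (disable only for
#'   architecture accounting experiments).
#' @param useDfc include the DFC attention branch in every Ghost module.
#' @return A \linkS4class{SegNetwork}.
#' @examples
#' net <- buildMSGUNet(seed = 1)
#' countParams(net)
#' @export
buildMSGUNet <- function(config = networkConfig(), seed = 1L,
                         useEla = TRUE, useDfc = TRUE) {
  validObject(config)
  new_network("msgunet", config, arch_msgunet(config, useEla, useDfc), seed)
}

#' Build the plain U-Net baseline
#'
#' The canonical U-Net used for the cost comparison: five stages of two 3x3
#' convolutions (batch norm + ReLU) with channels 64/128/256/512/1024, 2x2
#' max pooling, bilinear 2x2 up-sampling, skip concatenation without channel
#' halving, and a 1x1 single-logit head.
#'
#' @param seed integer initialisation seed.
#' @param config optional \linkS4class{NetworkConfig}; defaults to the
#'   canonical 64..1024 geometry.
#' @return A \linkS4class{SegNetwork}.
#' @export
buildUNetBaseline <- function(seed = 1L, config = networkConfig(
                                stageChannels = c(64, 128, 256, 512, 1024))) {
  validObject(config)
  new_network("unet", config, arch_unet(config), seed)
}

# named layer map for a network
layer_map <- function(net) {
  L <- net@arch$layers
  names(L) <- vapply(L, `[[`, "", "name")
  L
}

forward_msgunet <- function(net, x, ctx, P, BN, training) {
  L <- layer_map(net)
  useEla <- isTRUE(net@arch$opts$useEla)
  useDfc <- isTRUE(net@arch$opts$useDfc)
  h <- x
  skips <- vector("list", 4L)
  for (i in 1:4) {
    h <- fwd_spp(ctx, h, L, P, BN, sprintf("enc%d.spp", i), training)
    h <- fwd_ghost(ctx, h, L, P, BN, sprintf("enc%d.ghost", i), training,
                   dfc = useDfc)
    if (useEla)
      h <- fwd_ela(ctx, h, L, P, BN, sprintf("enc%d.ela", i), training)
    skips[[i]] <- h
    h <- ag_maxpool(ctx, h, c(2L, 2L), c(2L, 2L))
  }
  h <- fwd_ghost(ctx, h, L, P, BN, "enc5.ghost", training, dfc = useDfc)
  if (useEla)
    h <- fwd_ela(ctx, h, L, P, BN, "enc5.ela", training)
  for (i in 4:1) {
    d <- dim(vof(skips[[i]]))
    up <- ag_bilinear(ctx, h, d[1L], d[2L])
    gs <- fwd_gate(ctx, skips[[i]], up, L, P, BN, sprintf("dec%d.gate", i),
                   training)
    h <- ag_concat_c(ctx, gs, up)
    h <- fwd_ghost(ctx, h, L, P, BN, sprintf("dec%d.ghost", i), training,
                   dfc = useDfc)
  }
  run_conv(ctx, h, L[["head"]], P, BN, training)
}

forward_unet <- function(net, x, ctx, P, BN, training) {
  L <- layer_map(net)
  h <- x
  skips <- vector("list", 4L)
  for (i in 1:5) {
    h <- run_conv(ctx, h, L[[sprintf("enc%d.c1", i)]], P, BN, training)
    h <- run_conv(ctx, h, L[[sprintf("enc%d.c2", i)]], P, BN, training)
    if (i < 5) {
      skips[[i]] <- h
      h <- ag_maxpool(ctx, h, c(2L, 2L), c(2L, 2L))
    }
  }
  for (i in 4:1) {
    d <- dim(vof(skips[[i]]))
    up <- ag_bilinear(ctx, h, d[1L], d[2L])
    h <- ag_concat_c(ctx, skips[[i]], up)
    h <- run_conv(ctx, h, L[[sprintf("dec%d.c1", i)]], P, BN, training)
    h <- run_conv(ctx, h, L[[sprintf("dec%d.c2", i)]], P, BN, training)
  }
  run_conv(ctx, h, L[["head"]], P, BN, training)
}

# Shared forward dispatcher.  `leaves` (an environment of autograd nodes)
# replaces the raw parameter store during training.
net_forward_impl <- function(net, x, ctx = NULL, training = FALSE,
                             leaves = NULL) {
  store <- leaves %||% net@params
  P <- function(nm) get(nm, envir = store, inherits = FALSE)
  BN <- function(nm) get(nm, envir = net@buffers, inherits = FALSE)
  fwd <- switch(net@kind, msgunet = forward_msgunet, unet = forward_unet,
                stop("unknown network kind: ", net@kind))
  fwd(net, x, ctx, P, BN, training)
}

#' @rdname netForward
#' @export
setMethod("netForward", "SegNetwork", function(net, x, mode = "eval") {
  mode <- match.arg(mode, c("eval", "train"))
  check_fmap(x, net@config@inChannels)
  d <- dim(x)
  if (d[1L] %% 16 != 0 || d[2L] %% 16 != 0)
    stop("input spatial size (", d[1L], "x", d[2L],
         ") must be divisible by 16")
  out <- net_forward_impl(net, x, ctx = NULL, training = mode == "train")
  if (!all(is.finite(out))) stop("forward pass produced non-finite values")
  out
})

## ---- checkpoints ----

#' Save a network checkpoint
#'
#' Writes a single serialized weight archive plus a JSON sidecar
#' (\code{<path>.json}) recording the kind, configuration, seed and package
#' version.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param path file path for the archive.
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(net, path) {
  buffers <- lapply(as.list(net@buffers, all.names = TRUE),
                    function(st) list(rm = st$rm, rv = st$rv))
  obj <- list(kind = net@kind,
              stageChannels = net@config@stageChannels,
              inChannels = net@config@inChannels,
              outChannels = net@config@outChannels,
              inputSize = net@config@inputSize,
              seed = net@seed,
              opts = net@arch$opts,
              params = as.list(net@params, all.names = TRUE),
              buffers = buffers)
  saveRDS(obj, path)
  meta <- list(kind = net@kind, stageChannels = net@config@stageChannels,
               inChannels = net@config@inChannels,
               outChannels = net@config@outChannels,
               inputSize = net@config@inputSize, seed = net@seed,
               version = as.character(utils::packageVersion("msgunet")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path path written by \code{\link{saveCheckpoint}}.
#' @return A \linkS4class{SegNetwork} with the stored weights and buffers.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  config <- networkConfig(obj$stageChannels, obj$inChannels, obj$outChannels,
                          obj$inputSize)
  net <- if (obj$kind == "msgunet") {
    buildMSGUNet(config, seed = obj$seed,
                 useEla = isTRUE(obj$opts$useEla),
                 useDfc = isTRUE(obj$opts$useDfc))
  } else {
    buildUNetBaseline(seed = obj$seed, config = config)
  }
  for (nm in names(obj$params)) assign(nm, obj$params[[nm]], envir = net@params)
  for (nm in names(obj$buffers)) {
    st <- get(nm, envir = net@buffers, inherits = FALSE)
    st$rm <- obj$buffers[[nm]]$rm
    st$rv <- obj$buffers[[nm]]$rv
  }
  net
}
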
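# Building blocks: SPP-Inception, Ghost module with DFC attention, efficient
# local attention (ELA), and the attention gate.  Each block is described by
# an ordered list of layer descriptors; the same descriptors drive weight
# initialisation, the forward pass and the cost profiler, so the three can
# never drift apart.

## ---- layer descriptors ----

conv_layer <- function(name, cin, cout, kh, kw, pad, groups = 1L,
                       bias = FALSE, bn = TRUE, act = "relu",
                       div = 1L, spatial = "2d", dfc = FALSE) {
  list(kind = "conv", name = name, cin = as.integer(cin),
       cout = as.integer(cout), kh = as.integer(kh), kw = as.integer(kw),
       pad = as.integer(pad), groups = as.integer(groups), bias = bias,
       bn = bn, act = act, div = as.integer(div), spatial = spatial,
       dfc = dfc)
}

gn_layer <- function(name, channels, groups = 16L) {
  list(kind = "gn", name = name, channels = as.integer(channels),
       groups = as.integer(groups))
}

# He-normal initialisation for conv kernels; unit scale / zero shift for
# normalisation layers.  Draws from the current RNG stream.
init_layers <- function(layers, params, buffers) {
  for (ly in layers) {
    if (ly$kind == "conv") {
      cing <- ly$cin %/% ly$groups
      fan_in <- cing * ly$kh * ly$kw
      w <- array(stats::rnorm(ly$kh * ly$kw * cing * ly$cout,
                              sd = sqrt(2 / fan_in)),
                 c(ly$kh, ly$kw, cing, ly$cout))
      assign(paste0(ly$name, ".W"), w, envir = params)
      if (ly$bias)
        assign(paste0(ly$name, ".b"), numeric(ly$cout), envir = params)
      if (ly$bn) {
        assign(paste0(ly$name, ".bn.gamma"), rep(1, ly$cout), envir = params)
        assign(paste0(ly$name, ".bn.beta"), numeric(ly$cout), envir = params)
        st <- new.env(parent = emptyenv())
        st$rm <- numeric(ly$cout)
        st$rv <- rep(1, ly$cout)
        assign(paste0(ly$name, ".bn"), st, envir = buffers)
      }
    } else if (ly$kind == "gn") {
      assign(paste0(ly$name, ".gamma"), rep(1, ly$channels), envir = params)
      assign(paste0(ly$name, ".beta"), numeric(ly$channels), envir = params)
    }
  }
  invisible(NULL)
}

# conv -> (batch norm) -> activation, driven by one descriptor
run_conv <- function(ctx, x, ly, P, BN, training) {
  b <- if (ly$bias) P(paste0(ly$name, ".b")) else NULL
  y <- ag_conv2d(ctx, x, P(paste0(ly$name, ".W")), b,
                 pad = ly$pad, groups = ly$groups)
  if (ly$bn)
    y <- ag_batchnorm(ctx, y, P(paste0(ly$name, ".bn.gamma")),
                      P(paste0(ly$name, ".bn.beta")),
                      BN(paste0(ly$name, ".bn")), training)
  switch(ly$act,
         relu = ag_relu(ctx, y),
         sigmoid = ag_sigmoid(ctx, y),
         none = y,
         stop("unknown activation"))
}

## ---- SPP-Inception ----
# Four parallel branches, each emitting out/4 channels so the concatenation
# needs no projection: 1x1; 3x3; 5x5; 3x3 max-pool (stride 1) -> 1x1.
# Every convolution carries batch norm + ReLU.

spp_layers <- function(pre, cin, cout, div = 1L) {
  if (cout %% 4 != 0)
    stop("SPP-Inception: out channels (", cout, ") must be divisible by 4")
  q <- cout %/% 4
  list(conv_layer(paste0(pre, ".b1"), cin, q, 1, 1, c(0, 0), div = div),
       conv_layer(paste0(pre, ".b2"), cin, q, 3, 3, c(1, 1), div = div),
       conv_layer(paste0(pre, ".b3"), cin, q, 5, 5, c(2, 2), div = div),
       conv_layer(paste0(pre, ".b4"), cin, q, 1, 1, c(0, 0), div = div))
}

fwd_spp <- function(ctx, x, L, P, BN, pre, training) {
  b1 <- run_conv(ctx, x, L[[paste0(pre, ".b1")]], P, BN, training)
  b2 <- run_conv(ctx, x, L[[paste0(pre, ".b2")]], P, BN, training)
  b3 <- run_conv(ctx, x, L[[paste0(pre, ".b3")]], P, BN, training)
  p <- ag_maxpool(ctx, x, c(3L, 3L), c(1L, 1L), c(1L, 1L))
  b4 <- run_conv(ctx, p, L[[paste0(pre, ".b4")]], P, BN, training)
  ag_concat_c(ctx, ag_concat_c(ctx, b1, b2), ag_concat_c(ctx, b3, b4))
}

## ---- Ghost module with DFC attention ----
# Intrinsic half from a pointwise conv, ghost half from a 3x3 depthwise conv
# on the intrinsic features, concatenated; the decoupled fully-connected
# (DFC) branch computes a spatial sigmoid gate at half resolution
# (2x2 average pool -> 1x1 conv -> (1,5) and (5,1) depthwise convs, each with
# batch norm) and is bilinearly resampled back before gating the output.

ghost_layers <- function(pre, cin, cout, div = 1L, dfc = TRUE) {
  if (cout %% 2 != 0)
    stop("Ghost module: out channels (", cout, ") must be even")
  m <- cout %/% 2
  ls <- list(
    conv_layer(paste0(pre, ".primary"), cin, m, 1, 1, c(0, 0), div = div),
    conv_layer(paste0(pre, ".cheap"), m, m, 3, 3, c(1, 1), groups = m,
               div = div))
  if (dfc) {
    ls <- c(ls, list(
      conv_layer(paste0(pre, ".dfc1"), cin, cout, 1, 1, c(0, 0), act = "none",
                 div = div, dfc = TRUE),
      conv_layer(paste0(pre, ".dfch"), cout, cout, 1, 5, c(0, 2),
                 groups = cout, act = "none", div = div, dfc = TRUE),
      conv_layer(paste0(pre, ".dfcv"), cout, cout, 5, 1, c(2, 0),
                 groups = cout, act = "none", div = div, dfc = TRUE)))
  }
  ls
}

fwd_dfc <- function(ctx, x, L, P, BN, pre, training) {
  d <- dim(vof(x))
  if (d[1L] < 2L || d[2L] < 2L)
    stop("DFC attention: input spatial size must be at least 2x2")
  z <- ag_avgpool2(ctx, x)
  z <- run_conv(ctx, z, L[[paste0(pre, ".dfc1")]], P, BN, training)
  z <- run_conv(ctx, z, L[[paste0(pre, ".dfch")]], P, BN, training)
  z <- run_conv(ctx, z, L[[paste0(pre, ".dfcv")]], P, BN, training)
  z <- ag_sigmoid(ctx, z)
  ag_bilinear(ctx, z, d[1L], d[2L])
}

fwd_ghost <- function(ctx, x, L, P, BN, pre, training, dfc = TRUE) {
  y1 <- run_conv(ctx, x, L[[paste0(pre, ".primary")]], P, BN, training)
  y2 <- run_conv(ctx, y1, L[[paste0(pre, ".cheap")]], P, BN, training)
  y <- ag_concat_c(ctx, y1, y2)
  if (dfc) {
    gate <- fwd_dfc(ctx, x, L, P, BN, pre, training)
    y <- ag_mul(ctx, y, gate)
  }
  y
}

## ---- efficient local attention (ELA) ----
# Strip pooling along each axis, a per-channel 1-D convolution (kernel 7,
# padding 3), 16-group normalisation and a sigmoid produce separable height
# and width gates that rescale the input.

ela_layers <- function(pre, channels, div = 1L, gnGroups = 16L) {
  if (channels %% gnGroups != 0)
    stop("ELA: channels (", channels, ") must be divisible by the ",
         "group-norm group count (", gnGroups, ")")
  list(conv_layer(paste0(pre, ".h"), channels, channels, 7, 1, c(3, 0),
                  groups = channels, bn = FALSE, act = "none", div = div,
                  spatial = "striph"),
       gn_layer(paste0(pre, ".h.gn"), channels, gnGroups),
       conv_layer(paste0(pre, ".w"), channels, channels, 7, 1, c(3, 0),
                  groups = channels, bn = FALSE, act = "none", div = div,
                  spatial = "stripw"),
       gn_layer(paste0(pre, ".w.gn"), channels, gnGroups))
}

fwd_ela <- function(ctx, x, L, P, BN, pre, training) {
  gh <- L[[paste0(pre, ".h.gn")]]
  gw <- L[[paste0(pre, ".w.gn")]]
  zh <- ag_strip_h(ctx, x)                                   # (H,1,C,N)
  zw <- ag_strip_w(ctx, x)                                   # (W,1,C,N)
  yh <- run_conv(ctx, zh, L[[paste0(pre, ".h")]], P, BN, training)
  yh <- ag_groupnorm(ctx, yh, P(paste0(pre, ".h.gn.gamma")),
                     P(paste0(pre, ".h.gn.beta")), gh$groups)
  yh <- ag_sigmoid(ctx, yh)
  yw <- run_conv(ctx, zw, L[[paste0(pre, ".w")]], P, BN, training)
  yw <- ag_groupnorm(ctx, yw, P(paste0(pre, ".w.gn.gamma")),
                     P(paste0(pre, ".w.gn.beta")), gw$groups)
  yw <- ag_sigmoid(ctx, yw)
  ag_mul_w(ctx, ag_mul_h(ctx, x, yh), yw)
}

## ---- attention gate ----
# 1x1 projections of the gating signal (A) and the skip (B) are added,
# ReLU'd, collapsed to one channel and squashed to a per-patch weight in
# (0, 1) that rescales the skip features.

gate_layers <- function(pre, cskip, cgate, inter, div = 1L) {
  list(conv_layer(paste0(pre, ".A"), cgate, inter, 1, 1, c(0, 0), bias = TRUE,
                  bn = FALSE, act = "none", div = div),
       conv_layer(paste0(pre, ".B"), cskip, inter, 1, 1, c(0, 0), bias = TRUE,
                  bn = FALSE, act = "none", div = div),
       conv_layer(paste0(pre, ".psi"), inter, 1, 1, 1, c(0, 0), bias = TRUE,
                  bn = FALSE, act = "none", div = div))
}

fwd_gate <- function(ctx, skip, gating, L, P, BN, pre, training) {
  ds <- dim(vof(skip)); dg <- dim(vof(gating))
  if (!identical(ds[c(1L, 2L)], dg[c(1L, 2L)]))
    stop("attention gate: skip and gating spatial sizes differ")
  a <- run_conv(ctx, gating, L[[paste0(pre, ".A")]], P, BN, training)
  b <- run_conv(ctx, skip, L[[paste0(pre, ".B")]], P, BN, training)
  s <- ag_relu(ctx, ag_add(ctx, a, b))
  w <- ag_sigmoid(ctx, run_conv(ctx, s, L[[paste0(pre, ".psi")]], P, BN,
                                training))
  ag_mul_c(ctx, skip, w)
}

## ---- standalone block API ----

# A self-contained block: descriptors plus freshly initialised parameters.
new_block <- function(layers, seed) {
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  with_seed(seed, init_layers(layers, params, buffers))
  L <- layers
  names(L) <- vapply(layers, `[[`, "", "name")
  structure(list(layers = L, params = params, buffers = buffers),
            class = "msgu_block")
}

block_env <- function(block) {
  P <- function(nm) get(nm, envir = block$params, inherits = FALSE)
  BN <- function(nm) get(nm, envir = block$buffers, inherits = FALSE)
  list(P = P, BN = BN)
}

check_fmap <- function(x, channels = NULL, what = "input") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be an (H, W, C, N) array")
  if (any(dim(x) < 1L)) stop(what, " has an empty dimension")
  if (!is.null(channels) && dim(x)[3L] != channels)
    stop(what, " has ", dim(x)[3L], " channels; block expects ", channels)
  invisible(NULL)
}

#' SPP-Inception block
#'
#' Four-branch multi-scale convolution block (1x1; 3x3; 5x5; 3x3 max-pool
#' followed by 1x1), each branch emitting a quarter of the output channels so
#' the channel concatenation needs no projection.  Every convolution is
#' followed by batch normalisation and ReLU.
#'
#' @param inChannels,outChannels channel counts; \code{outChannels} must be
#'   divisible by 4.
#' @param seed seed for weight initialisation.
#' @return a block object usable with \code{\link{sppInceptionForward}}.
#' @examples
#' blk <- sppInceptionBlock(8, 32)
#' y <- sppInceptionForward(blk, array(rnorm(8 * 16 * 16), c(16, 16, 8, 1)))
#' dim(y)  # 16 16 32 1
#' @export
sppInceptionBlock <- function(inChannels, outChannels, seed = 1L) {
  blk <- new_block(spp_layers("spp", inChannels, outChannels), seed)
  blk$inChannels <- inChannels
  blk$outChannels <- outChannels
  blk
}

#' Forward pass of an SPP-Inception block
#'
#' @param block object from \code{\link{sppInceptionBlock}}.
#' @param x input (H, W, C, N) array.
#' @param training use batch statistics (TRUE) or running moments (FALSE).
#' @return (H, W, outChannels, N) array; the spatial size is preserved.
#' @export
sppInceptionForward <- function(block, x, training = FALSE) {
  check_fmap(x, block$inChannels)
  e <- block_env(block)
  fwd_spp(NULL, x, block$layers, e$P, e$BN, "spp", training)
}

#' Ghost module with optional DFC attention
#'
#' @param inChannels,outChannels channel counts; \code{outChannels} must be
#'   even (the intrinsic half is \code{outChannels / 2}).
#' @param dfc include the decoupled fully-connected attention branch.
#' @param seed seed for weight initialisation.
#' @return a block object for \code{\link{ghostForward}} /
#'   \code{\link{dfcAttention}}.
#' @export
ghostBlock <- function(inChannels, outChannels, dfc = TRUE, seed = 1L) {
  blk <- new_block(ghost_layers("ghost", inChannels, outChannels, dfc = dfc),
                   seed)
  blk$inChannels <- inChannels
  blk$outChannels <- outChannels
  blk$dfc <- dfc
  blk
}

#' Forward pass of a Ghost module
#'
#' Concatenates the pointwise (intrinsic) half with its 3x3 depthwise ghost
#' half and, when the block carries DFC attention, multiplies by the spatial
#' gate.
#'
#' @inheritParams sppInceptionForward
#' @return (H, W, outChannels, N) array.
#' @export
ghostForward <- function(block, x, training = FALSE) {
  check_fmap(x, block$inChannels)
  e <- block_env(block)
  fwd_ghost(NULL, x, block$layers, e$P, e$BN, "ghost", training,
            dfc = isTRUE(block$dfc))
}

#' DFC attention gate of a Ghost module
#'
#' The decoupled fully-connected attention branch alone: 2x2 average pooling,
#' 1x1 convolution, (1,5) and (5,1) depthwise convolutions (batch norm after
#' each), sigmoid, and bilinear up-sampling back to the input size.
#'
#' @inheritParams sppInceptionForward
#' @return gate array (H, W, outChannels, N) with all values in (0, 1).
#' @export
dfcAttention <- function(block, x, training = FALSE) {
  if (!isTRUE(block$dfc)) stop("block was built without a DFC branch")
  check_fmap(x, block$inChannels)
  e <- block_env(block)
  fwd_dfc(NULL, x, block$layers, e$P, e$BN, "ghost", training)
}

#' Strip pooling
#'
#' Per-channel average pooling along exactly one spatial axis: the horizontal
#' descriptor holds row means (length H), the vertical descriptor column
#' means (length W).
#'
#' @param x input (H, W, C, N) array.
#' @return list with \code{horiz} (H, 1, C, N) and \code{vert} (W, 1, C, N).
#' @examples
#' x <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))  # [[1,2],[3,4]] row-major
#' stripPool(x)$horiz[, 1, 1, 1]  # 1.5 3.5
#' @export
stripPool <- function(x) {
  check_fmap(x)
  list(horiz = ag_strip_h(NULL, x), vert = ag_strip_w(NULL, x))
}

#' Efficient local attention (ELA) block
#'
#' @param channels feature channels; must be divisible by \code{gnGroups}.
#' @param gnGroups group count of the group normalisation (default 16).
#' @param seed seed for weight initialisation.
#' @return a block object for \code{\link{elaForward}}.
#' @export
elaBlock <- function(channels, gnGroups = 16L, seed = 1L) {
  blk <- new_block(ela_layers("ela", channels, gnGroups = gnGroups), seed)
  blk$channels <- channels
  blk
}

#' Forward pass of an ELA block
#'
#' Strip pooling along each axis, per-channel 1-D convolution (kernel 7),
#' group normalisation and sigmoid give separable height/width gates in
#' (0, 1); the output is the input rescaled by both gates.
#'
#' @inheritParams sppInceptionForward
#' @return array of the same shape as \code{x}.
#' @export
elaForward <- function(block, x, training = FALSE) {
  check_fmap(x, block$channels)
  e <- block_env(block)
  fwd_ela(NULL, x, block$layers, e$P, e$BN, "ela", training)
}

#' Attention gate block
#'
#' @param skipChannels,gatingChannels channels of the skip and gating inputs.
#' @param interChannels intermediate width of the additive attention;
#'   defaults to a quarter of the skip channels.
#' @param seed seed for weight initialisation.
#' @return a block object for \code{\link{attentionGateForward}}.
#' @export
attentionGateBlock <- function(skipChannels, gatingChannels,
                               interChannels = max(1L, skipChannels %/% 4L),
                               seed = 1L) {
  blk <- new_block(gate_layers("gate", skipChannels, gatingChannels,
                               interChannels), seed)
  blk$skipChannels <- skipChannels
  blk$gatingChannels <- gatingChannels
  blk
}

#' Forward pass of an attention gate
#'
#' Adds 1x1 projections of gating signal and skip, applies ReLU, collapses to
#' a single channel and squashes with a sigmoid; the per-patch weight in
#' (0, 1) rescales the skip features.
#'
#' @param block object from \code{\link{attentionGateBlock}}.
#' @param skip skip feature map (H, W, skipChannels, N).
#' @param gating gating feature map (H, W, gatingChannels, N); must match the
#'   skip's spatial size.
#' @param training unused (the gate has no batch norm); kept for symmetry.
#' @return gated skip, same shape as \code{skip}.
#' @export
attentionGateForward <- function(block, skip, gating, training = FALSE) {
  check_fmap(skip, block$skipChannels, "skip")
  check_fmap(gating, block$gatingChannels, "gating")
  e <- block_env(block)
  fwd_gate(NULL, skip, gating, block$layers, e$P, e$BN, "gate", training)
}
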
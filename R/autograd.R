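# Reverse-mode automatic differentiation over (H, W, C, N) arrays.
#
# A tape (`ag_ctx`) records every differentiable operation in creation order;
# nodes are environments holding the forward value, the accumulated gradient,
# the parent inputs and a backward closure.  Because the graph is built
# forward, reverse creation order is a valid topological order for the
# backward sweep.  Every op also works with `ctx = NULL` on plain arrays,
# which is the inference path (no tape, no closures).

ag_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- vector("list", 512L)
  ctx$n <- 0L
  ctx
}

is_node <- function(x) is.environment(x)

# value-of: unwrap a node to its array
vof <- function(x) if (is.environment(x)) x$value else x

ag_leaf <- function(ctx, value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- NULL
  node$backfn <- NULL
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$nodes)) length(ctx$nodes) <- 2L * ctx$n
  ctx$nodes[[ctx$n]] <- node
  node
}

# Register an op result.  When no input is a node (or there is no tape) the
# raw value is returned and nothing is recorded.
agop <- function(ctx, inputs, value, backfn) {
  if (is.null(ctx)) return(value)
  if (!any(vapply(inputs, is_node, logical(1)))) return(value)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- inputs
  node$backfn <- backfn
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$nodes)) length(ctx$nodes) <- 2L * ctx$n
  ctx$nodes[[ctx$n]] <- node
  node
}

# Backward sweep from `loss` (a scalar node).  Gradients accumulate on every
# node; leaves keep theirs, interior nodes are freed as the sweep passes.
ag_backward <- function(ctx, loss) {
  stopifnot(is_node(loss))
  loss$grad <- 1
  for (i in rev(seq_len(ctx$n))) {
    nd <- ctx$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!is_node(p)) next
      gk <- gs[[k]]
      if (is.null(gk)) next
      p$grad <- if (is.null(p$grad)) gk else p$grad + gk
    }
    nd$grad <- NULL
    nd$backfn <- NULL
    nd$parents <- NULL
  }
  invisible(NULL)
}

## ---- primitive ops ----

ag_conv2d <- function(ctx, x, w, b = NULL, pad = c(0L, 0L), groups = 1L) {
  xv <- vof(x); wv <- vof(w)
  bv <- if (is.null(b)) NULL else vof(b)
  dw <- is.null(bv) && groups == dim(xv)[3L] && dim(wv)[3L] == 1L &&
    dim(wv)[4L] == groups
  if (dw) {
    out <- cpp_dwconv_fwd(xv, wv, pad[1L], pad[2L])
    return(agop(ctx, list(x, w, b), out, function(g) {
      r <- cpp_dwconv_bwd(xv, wv, g, pad[1L], pad[2L], is_node(x))
      list(r$gx, r$gw, NULL)
    }))
  }
  out <- cpp_conv2d_fwd(xv, wv, bv, pad[1L], pad[2L], groups)
  agop(ctx, list(x, w, b), out, function(g) {
    need_gx <- is_node(x)
    r <- cpp_conv2d_bwd(xv, wv, g, pad[1L], pad[2L], groups,
                        need_gx, !is.null(bv))
    list(r$gx, r$gw, r$gb)
  })
}

ag_relu <- function(ctx, x) {
  xv <- vof(x)
  out <- pmax(xv, 0)
  dim(out) <- dim(xv)
  agop(ctx, list(x), out, function(g) list(g * (xv > 0)))
}

ag_sigmoid <- function(ctx, x) {
  xv <- vof(x)
  out <- 1 / (1 + exp(-xv))
  dim(out) <- dim(xv)
  agop(ctx, list(x), out, function(g) list(g * out * (1 - out)))
}

ag_add <- function(ctx, a, b) {
  agop(ctx, list(a, b), vof(a) + vof(b), function(g) list(g, g))
}

ag_mul <- function(ctx, a, b) {
  av <- vof(a); bv <- vof(b)
  agop(ctx, list(a, b), av * bv, function(g) list(g * bv, g * av))
}

# concatenate along the channel dimension (dim 3)
ag_concat_c <- function(ctx, a, b) {
  av <- vof(a); bv <- vof(b)
  ca <- dim(av)[3L]; cb <- dim(bv)[3L]
  out <- cpp_concat_c(av, bv)
  agop(ctx, list(a, b), out, function(g) list(
    cpp_slice_c(g, 0L, ca),
    cpp_slice_c(g, ca, cb)))
}

ag_maxpool <- function(ctx, x, k, stride, pad = c(0L, 0L)) {
  xv <- vof(x)
  r <- cpp_maxpool_fwd(xv, k[1L], k[2L], stride[1L], stride[2L],
                       pad[1L], pad[2L])
  agop(ctx, list(x), r$out, function(g) {
    list(cpp_maxpool_bwd(g, r$argmax, dim(xv)))
  })
}

ag_avgpool2 <- function(ctx, x) {
  xv <- vof(x)
  agop(ctx, list(x), cpp_avgpool2_fwd(xv), function(g) {
    list(cpp_avgpool2_bwd(g, dim(xv)))
  })
}

ag_bilinear <- function(ctx, x, oh, ow) {
  xv <- vof(x)
  d <- dim(xv)
  out <- cpp_bilinear_fwd(xv, oh, ow)
  agop(ctx, list(x), out, function(g) list(cpp_bilinear_bwd(g, d[1L], d[2L])))
}

# swap the two spatial dims: (A, B, C, N) -> (B, A, C, N); its own inverse
ag_permute12 <- function(ctx, x) {
  out <- aperm(vof(x), c(2L, 1L, 3L, 4L))
  agop(ctx, list(x), out, function(g) list(aperm(g, c(2L, 1L, 3L, 4L))))
}

## ---- reductions along one spatial axis (strip pooling) ----

ag_strip_h <- function(ctx, x) {
  xv <- vof(x); d <- dim(xv)
  out <- cpp_sum_w(xv) / d[2L]
  agop(ctx, list(x), out, function(g) {
    list(g[, rep(1L, d[2L]), , , drop = FALSE] / d[2L])
  })
}

ag_strip_w <- function(ctx, x) {
  xv <- vof(x); d <- dim(xv)
  out <- cpp_sum_h(xv) / d[1L]
  agop(ctx, list(x), out, function(g) {
    list(array(rep(as.vector(g), each = d[1L]), d) / d[1L])
  })
}

## ---- broadcast multiplications for the separable / per-patch gates ----

# x (H,W,C,N) times a height gate (H,1,C,N), broadcast over width
ag_mul_h <- function(ctx, x, yh) {
  xv <- vof(x); yv <- vof(yh)
  agop(ctx, list(x, yh), cpp_mul_h(xv, yv), function(g) {
    list(cpp_mul_h(g, yv), cpp_sum_w(g * xv))
  })
}

# x (H,W,C,N) times a width gate (W,1,C,N), broadcast over height
ag_mul_w <- function(ctx, x, yw) {
  xv <- vof(x); yv <- vof(yw)
  agop(ctx, list(x, yw), cpp_mul_w(xv, yv), function(g) {
    list(cpp_mul_w(g, yv), cpp_sum_h(g * xv))
  })
}

# x (H,W,C,N) times a single-channel spatial gate (H,W,1,N)
ag_mul_c <- function(ctx, x, gate) {
  xv <- vof(x); gv <- vof(gate)
  agop(ctx, list(x, gate), cpp_mul_c(xv, gv), function(g) {
    list(cpp_mul_c(g, gv), cpp_sum_c(g * xv))
  })
}

## ---- normalisation layers ----

# Batch normalisation.  Training mode normalises with batch statistics
# (biased variance, as is conventional) and updates the running moments held
# in `state`; eval mode applies the running moments as a fixed affine map.
ag_batchnorm <- function(ctx, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- vof(x); d <- dim(xv)
  hw <- d[1L] * d[2L]
  m <- hw * d[4L]
  gv <- vof(gamma); bv <- vof(beta)
  if (training) {
    st <- cpp_channel_stats(xv)
    mu <- st$sum / m
    va <- pmax(st$sumsq / m - mu^2, 0)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv +
      momentum * va * (if (m > 1) m / (m - 1) else 1)
  } else {
    mu <- state$rm
    va <- state$rv
  }
  istd <- 1 / sqrt(va + eps)
  out <- cpp_affine_c(xv, gv * istd, bv - mu * gv * istd)
  agop(ctx, list(x, gamma, beta), out, function(g) {
    if (training) {
      r <- cpp_bn_bwd(g, xv, mu, istd, gv)
      list(r$dx, r$dgamma, r$dbeta)
    } else {
      xhat <- cpp_affine_c(xv, istd, -mu * istd)
      list(cpp_affine_c(g, gv * istd, numeric(d[3L])),
           cpp_channel_sums(g * xhat), cpp_channel_sums(g))
    }
  })
}

# Group normalisation: statistics per (sample, channel group) over H, W and
# the group's channels.  No running state; deterministic in both modes.
ag_groupnorm <- function(ctx, x, gamma, beta, groups, eps = 1e-5) {
  xv <- vof(x); d <- dim(xv)
  if (d[3L] %% groups != 0L)
    stop("groupnorm: channels (", d[3L], ") not divisible by groups (",
         groups, ")")
  hw <- d[1L] * d[2L]
  cg <- d[3L] %/% groups
  m <- hw * cg
  gv <- vof(gamma); bv <- vof(beta)
  xm <- matrix(xv, nrow = m)
  mu <- colMeans(xm)                       # length groups*N
  va <- pmax(colMeans(xm * xm) - mu^2, 0)
  istd <- 1 / sqrt(va + eps)
  mu_f <- rep(mu, each = m)
  istd_f <- rep(istd, each = m)
  xhat <- (xv - mu_f) * istd_f
  g_f <- rep(rep(gv, each = hw), times = d[4L])
  b_f <- rep(rep(bv, each = hw), times = d[4L])
  out <- xhat * g_f + b_f
  dim(out) <- d
  agop(ctx, list(x, gamma, beta), out, function(g) {
    dgamma <- cpp_channel_sums(g * xhat)
    dbeta <- cpp_channel_sums(g)
    dxhat <- g * g_f
    t1 <- rep(colMeans(matrix(dxhat, nrow = m)), each = m)
    t2 <- rep(colMeans(matrix(dxhat * xhat, nrow = m)), each = m)
    dx <- istd_f * (dxhat - t1 - xhat * t2)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# Numerically stable binary cross-entropy on logits, averaged over all
# elements: mean(max(x, 0) - x*y + log(1 + exp(-|x|))).
ag_bce_logits <- function(ctx, logits, target) {
  xv <- vof(logits)
  if (!identical(dim(xv), dim(target)))
    stop("bce: logits and target shapes differ")
  val <- mean(pmax(xv, 0) - xv * target + log1p(exp(-abs(xv))))
  agop(ctx, list(logits), val, function(g) {
    list(g * (1 / (1 + exp(-xv)) - target) / length(xv))
  })
}
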
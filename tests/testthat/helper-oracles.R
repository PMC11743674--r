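# Independent loop-based oracles used to cross-check the vectorised /
# compiled implementations.  Deliberately naive: explicit loops, no shared
# code with the package internals.

# plain 2-D convolution, stride 1, zero padding, channel groups
oracle_conv2d <- function(x, w, b = NULL, pad = c(0, 0), groups = 1) {
  d <- dim(x); kd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- kd[1]; kw <- kd[2]; cing <- kd[3]; cout <- kd[4]
  coutg <- cout / groups
  oH <- H + 2 * pad[1] - kh + 1
  oW <- W + 2 * pad[2] - kw + 1
  out <- array(0, c(oH, oW, cout, N))
  for (n in 1:N) for (oc in 1:cout) {
    g <- (oc - 1) %/% coutg
    for (oh in 1:oH) for (ow in 1:oW) {
      acc <- if (is.null(b)) 0 else b[oc]
      for (ci in 1:cing) for (ki in 1:kh) for (kj in 1:kw) {
        h <- oh - pad[1] + ki - 1
        wdx <- ow - pad[2] + kj - 1
        if (h >= 1 && h <= H && wdx >= 1 && wdx <= W)
          acc <- acc + x[h, wdx, g * cing + ci, n] * w[ki, kj, ci, oc]
      }
      out[oh, ow, oc, n] <- acc
    }
  }
  out
}

# eval-mode batch norm with moments (rm, rv)
oracle_bn <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in 1:d[3])
    out[, , c, ] <- (x[, , c, ] - rm[c]) / sqrt(rv[c] + eps) * gamma[c] +
      beta[c]
  out
}

oracle_relu <- function(x) { x[x < 0] <- 0; x }
oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 stride-2 average pooling (floor)
oracle_avgpool2 <- function(x) {
  d <- dim(x)
  oH <- d[1] %/% 2; oW <- d[2] %/% 2
  out <- array(0, c(oH, oW, d[3], d[4]))
  for (n in 1:d[4]) for (c in 1:d[3]) for (i in 1:oH) for (j in 1:oW)
    out[i, j, c, n] <- mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
  out
}

# bilinear resize, half-pixel convention, edges clamped
oracle_bilinear <- function(x, oH, oW) {
  d <- dim(x)
  out <- array(0, c(oH, oW, d[3], d[4]))
  axis <- function(inn, outn, i) {
    src <- (i - 0.5) * inn / outn - 0.5
    src <- min(max(src, 0), inn - 1)
    lo <- floor(src)
    c(lo + 1, min(lo + 2, inn), src - lo)
  }
  for (n in 1:d[4]) for (c in 1:d[3]) for (i in 1:oH) for (j in 1:oW) {
    ah <- axis(d[1], oH, i); aw <- axis(d[2], oW, j)
    fh <- ah[3]; fw <- aw[3]
    out[i, j, c, n] <-
      (1 - fh) * (1 - fw) * x[ah[1], aw[1], c, n] +
      fh * (1 - fw) * x[ah[2], aw[1], c, n] +
      (1 - fh) * fw * x[ah[1], aw[2], c, n] +
      fh * fw * x[ah[2], aw[2], c, n]
  }
  out
}

# Ghost module (eval mode, fresh moments rm=0, rv=1) evaluated step by step
# from a block's weight arrays: intrinsic pointwise half, depthwise ghost
# half, concatenation, then the DFC gate if present.
oracle_ghost <- function(block, x) {
  p <- function(nm) get(nm, envir = block$params)
  m <- dim(p("ghost.primary.W"))[4]
  y1 <- oracle_relu(oracle_bn(oracle_conv2d(x, p("ghost.primary.W")),
                              p("ghost.primary.bn.gamma"),
                              p("ghost.primary.bn.beta"),
                              numeric(m), rep(1, m)))
  y2 <- oracle_relu(oracle_bn(
    oracle_conv2d(y1, p("ghost.cheap.W"), pad = c(1, 1), groups = m),
    p("ghost.cheap.bn.gamma"), p("ghost.cheap.bn.beta"),
    numeric(m), rep(1, m)))
  d <- dim(y1)
  out <- array(0, c(d[1], d[2], 2 * m, d[4]))
  out[, , 1:m, ] <- y1
  out[, , m + 1:(m), ] <- y2
  if (isTRUE(block$dfc)) {
    cout <- 2 * m
    z <- oracle_avgpool2(x)
    z <- oracle_bn(oracle_conv2d(z, p("ghost.dfc1.W")),
                   p("ghost.dfc1.bn.gamma"), p("ghost.dfc1.bn.beta"),
                   numeric(cout), rep(1, cout))
    z <- oracle_bn(oracle_conv2d(z, p("ghost.dfch.W"), pad = c(0, 2),
                                 groups = cout),
                   p("ghost.dfch.bn.gamma"), p("ghost.dfch.bn.beta"),
                   numeric(cout), rep(1, cout))
    z <- oracle_bn(oracle_conv2d(z, p("ghost.dfcv.W"), pad = c(2, 0),
                                 groups = cout),
                   p("ghost.dfcv.bn.gamma"), p("ghost.dfcv.bn.beta"),
                   numeric(cout), rep(1, cout))
    gate <- oracle_bilinear(oracle_sigmoid(z), dim(x)[1], dim(x)[2])
    out <- out * gate
  }
  out
}

# ELA evaluated step by step: strip means, depthwise 1-D conv (kernel 7,
# padding 3), per-sample group norm, sigmoid, separable gating.
oracle_ela <- function(block, x, gnGroups = 16) {
  p <- function(nm) get(nm, envir = block$params)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  conv1d <- function(z, w) {   # z: len x C x N ; w: (7,1,1,C)
    L <- dim(z)[1]
    out <- array(0, dim(z))
    for (n in 1:N) for (c in 1:C) for (i in 1:L) {
      acc <- 0
      for (k in 1:7) {
        j <- i - 3 + k - 1
        if (j >= 1 && j <= L) acc <- acc + z[j, c, n] * w[k, 1, 1, c]
      }
      out[i, c, n] <- acc
    }
    out
  }
  gnorm <- function(z, gamma, beta, eps = 1e-5) {
    cg <- C / gnGroups
    out <- z
    for (n in 1:N) for (g in 1:gnGroups) {
      idx <- ((g - 1) * cg + 1):(g * cg)
      v <- z[, idx, n]
      mu <- mean(v)
      va <- mean((v - mu)^2)
      for (c in idx)
        out[, c, n] <- (z[, c, n] - mu) / sqrt(va + eps) * gamma[c] + beta[c]
    }
    out
  }
  zh <- array(0, c(H, C, N))
  zw <- array(0, c(W, C, N))
  for (n in 1:N) for (c in 1:C) {
    for (h in 1:H) zh[h, c, n] <- mean(x[h, , c, n])
    for (w in 1:W) zw[w, c, n] <- mean(x[, w, c, n])
  }
  yh <- oracle_sigmoid(gnorm(conv1d(zh, p("ela.h.W")),
                             p("ela.h.gn.gamma"), p("ela.h.gn.beta")))
  yw <- oracle_sigmoid(gnorm(conv1d(zw, p("ela.w.W")),
                             p("ela.w.gn.gamma"), p("ela.w.gn.beta")))
  out <- x
  for (n in 1:N) for (c in 1:C) for (h in 1:H) for (w in 1:W)
    out[h, w, c, n] <- x[h, w, c, n] * yh[h, c, n] * yw[w, c, n]
  out
}

# per-pixel confusion tally with explicit loops
oracle_metrics <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0.5
    t <- truth[i, j] > 0.5
    if (p && t) tp <- tp + 1
    else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_bce <- function(logits, y) {
  s <- 1 / (1 + exp(-logits))
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

# zero all weight arrays of a standalone block (normalisation scales kept)
zero_block_weights <- function(block) {
  for (nm in ls(block$params)) {
    if (grepl("\\.W$", nm) || grepl("\\.b$", nm))
      assign(nm, get(nm, envir = block$params) * 0, envir = block$params)
  }
  invisible(block)
}

rand_fmap <- function(h, w, c, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * n), c(h, w, c, n))
}
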
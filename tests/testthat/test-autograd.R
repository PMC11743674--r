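# Finite-difference validation of the reverse-mode gradients.  Central
# differences at eps = 1e-6; relative tolerance 1e-4 (kink-free test points).

ns <- asNamespace("msgunet")
ag_ctx <- get("ag_ctx", ns)
ag_leaf <- get("ag_leaf", ns)
ag_backward <- get("ag_backward", ns)

# make_loss(ctx, params_list) must return a scalar (node when ctx given)
fd_check <- function(make_loss, params, n_probe = 5L, eps = 1e-6) {
  ctx <- ag_ctx()
  leaves <- lapply(params, function(p) ag_leaf(ctx, p))
  ag_backward(ctx, make_loss(ctx, leaves))
  worst <- 0
  set.seed(1)
  for (k in seq_along(params)) {
    g <- leaves[[k]]$grad
    if (is.null(g)) g <- params[[k]] * 0
    for (i in sample(length(params[[k]]), min(n_probe, length(params[[k]])))) {
      pp <- params; pp[[k]][i] <- pp[[k]][i] + eps
      pm <- params; pm[[k]][i] <- pm[[k]][i] - eps
      num <- (make_loss(NULL, pp) - make_loss(NULL, pm)) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(1, abs(num)))
    }
  }
  worst
}

test_that("convolution gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(6 * 8 * 4 * 2), c(6, 8, 4, 2))
  w <- array(rnorm(3 * 3 * 2 * 6), c(3, 3, 2, 6))
  b <- rnorm(6)
  f <- function(ctx, p) {
    y <- get("ag_conv2d", ns)(ctx, p[[1]], p[[2]], p[[3]],
                              pad = c(1, 1), groups = 2)
    get("ag_bce_logits", ns)(ctx, y, array(0.3, c(6, 8, 6, 2)))
  }
  expect_lt(fd_check(f, list(x, w, b)), 1e-4)
  # depthwise fast path
  wd <- array(rnorm(7 * 1 * 1 * 4), c(7, 1, 1, 4))
  fd <- function(ctx, p) {
    y <- get("ag_conv2d", ns)(ctx, p[[1]], p[[2]], NULL,
                              pad = c(3, 0), groups = 4)
    get("ag_bce_logits", ns)(ctx, y, array(0.6, c(6, 8, 4, 2)))
  }
  expect_lt(fd_check(fd, list(x, wd)), 1e-4)
  # depthwise path agrees with the generic grouped path
  ns_f <- get("cpp_conv2d_fwd", ns)
  ref <- ns_f(x, wd, NULL, 3L, 0L, 4L)
  expect_equal(get("ag_conv2d", ns)(NULL, x, wd, pad = c(3, 0), groups = 4),
               ref, tolerance = 1e-12)
})

test_that("normalisation gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(5 * 5 * 4 * 3), c(5, 5, 4, 3))
  gamma <- runif(4, 0.5, 1.5)
  beta <- rnorm(4, sd = 0.2)
  f_bn <- function(ctx, p) {
    st <- new.env(); st$rm <- numeric(4); st$rv <- rep(1, 4)
    y <- get("ag_batchnorm", ns)(ctx, p[[1]], p[[2]], p[[3]], st, TRUE)
    get("ag_bce_logits", ns)(ctx, y, array(0.7, dim(x)))
  }
  expect_lt(fd_check(f_bn, list(x, gamma, beta)), 1e-4)
  f_gn <- function(ctx, p) {
    y <- get("ag_groupnorm", ns)(ctx, p[[1]], p[[2]], p[[3]], 2)
    get("ag_bce_logits", ns)(ctx, y, array(0.4, dim(x)))
  }
  expect_lt(fd_check(f_gn, list(x, gamma, beta)), 1e-4)
})

test_that("pooling, resampling, strip and broadcast gradients match finite differences", {
  set.seed(13)
  x <- array(rnorm(7 * 9 * 3 * 2), c(7, 9, 3, 2))
  f <- function(ctx, p) {
    h <- get("ag_maxpool", ns)(ctx, p[[1]], c(3, 3), c(1, 1), c(1, 1))
    h <- get("ag_avgpool2", ns)(ctx, h)
    h <- get("ag_bilinear", ns)(ctx, h, 7, 9)
    yh <- get("ag_sigmoid", ns)(ctx, get("ag_strip_h", ns)(ctx, h))
    yw <- get("ag_sigmoid", ns)(ctx, get("ag_strip_w", ns)(ctx, h))
    h <- get("ag_mul_w", ns)(ctx, get("ag_mul_h", ns)(ctx, h, yh), yw)
    get("ag_bce_logits", ns)(ctx, h, array(0.2, dim(x)))
  }
  expect_lt(fd_check(f, list(x), n_probe = 8L), 1e-4)
  # per-patch channel broadcast and concatenation
  w1 <- array(rnorm(3), c(1, 1, 3, 1))
  f2 <- function(ctx, p) {
    a <- get("ag_relu", ns)(ctx, p[[1]])
    g1 <- get("ag_sigmoid", ns)(
      ctx, get("ag_conv2d", ns)(ctx, a, p[[2]], NULL, pad = c(0, 0)))
    h <- get("ag_mul_c", ns)(ctx, a, g1)
    h <- get("ag_concat_c", ns)(ctx, h, a)
    get("ag_bce_logits", ns)(ctx, h, array(0.6, c(7, 9, 6, 2)))
  }
  expect_lt(fd_check(f2, list(x, w1), n_probe = 8L), 1e-4)
})

test_that("BCE-with-logits gradient is sigmoid(x) minus target, averaged", {
  set.seed(14)
  x <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  y <- array(rbinom(32, 1, 0.5), c(4, 4, 1, 2))
  ctx <- ag_ctx()
  leaf <- ag_leaf(ctx, x)
  loss <- get("ag_bce_logits", ns)(ctx, leaf, y)
  ag_backward(ctx, loss)
  expect_equal(leaf$grad, (1 / (1 + exp(-x)) - y) / length(x),
               tolerance = 1e-12)
})
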
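test_that("SPP-Inception splits channels four ways and preserves spatial size", {
  for (cout in c(4L, 16L, 64L, 512L)) {
    blk <- sppInceptionBlock(3L, cout, seed = cout)
    y <- sppInceptionForward(blk, rand_fmap(6, 6, 3, 1, seed = cout))
    expect_identical(dim(y), c(6L, 6L, cout, 1L))
  }
  blk <- sppInceptionBlock(8L, 32L, seed = 2)
  y <- sppInceptionForward(blk, rand_fmap(16, 16, 8, 1, seed = 2))
  expect_identical(dim(y), c(16L, 16L, 32L, 1L))
  # quarter-channel branch accounting: each branch owns out/4 channels;
  # zeroing one branch's kernel silences exactly its quarter
  assign("spp.b2.W", get("spp.b2.W", envir = blk$params) * 0,
         envir = blk$params)
  y2 <- sppInceptionForward(blk, rand_fmap(16, 16, 8, 1, seed = 2))
  expect_true(all(y2[, , 9:16, ] == 0))
  expect_equal(y2[, , -(9:16), ], y[, , -(9:16), ])
  expect_error(sppInceptionBlock(8L, 30L), "divisible by 4")
})

test_that("SPP-Inception with zero weights emits ReLU(0) = 0 everywhere", {
  blk <- zero_block_weights(sppInceptionBlock(4L, 8L))
  y <- sppInceptionForward(blk, rand_fmap(8, 8, 4, 2, seed = 1))
  expect_true(all(y == 0))
})

test_that("Ghost module keeps the channel bookkeeping of its two halves", {
  blk <- ghostBlock(32L, 16L, dfc = FALSE, seed = 3)
  x <- rand_fmap(8, 8, 32, 1, seed = 3)
  y <- ghostForward(blk, x)
  expect_identical(dim(y), c(8L, 8L, 16L, 1L))
  # intrinsic half reappears verbatim as the first 8 channels
  p <- blk$params
  y1 <- oracle_relu(oracle_bn(oracle_conv2d(x, get("ghost.primary.W", p)),
                              get("ghost.primary.bn.gamma", p),
                              get("ghost.primary.bn.beta", p),
                              numeric(8), rep(1, 8)))
  expect_equal(y[, , 1:8, , drop = FALSE], y1, tolerance = 1e-12)
  blk2 <- ghostBlock(32L, 64L, seed = 4)
  y <- ghostForward(blk2, rand_fmap(16, 16, 32, 2, seed = 4))
  expect_identical(dim(y), c(16L, 16L, 64L, 2L))
  expect_error(ghostBlock(8L, 15L), "even")
})

test_that("Ghost module on a 1x1 instance matches hand arithmetic", {
  blk <- ghostBlock(2L, 2L, dfc = FALSE, seed = 1)
  # make the batch norms exact identities: rm = 0, rv = 1, gamma = sqrt(1+eps)
  for (nm in c("ghost.primary.bn.gamma", "ghost.cheap.bn.gamma"))
    assign(nm, rep(sqrt(1 + 1e-5), 1L), envir = blk$params)
  assign("ghost.primary.W", array(c(2, -3), c(1, 1, 2, 1)),
         envir = blk$params)
  wd <- array(0, c(3, 3, 1, 1))
  wd[2, 2, 1, 1] <- 0.5          # only the centre tap can touch a 1x1 map
  assign("ghost.cheap.W", wd, envir = blk$params)
  x <- array(c(4, 1), c(1, 1, 2, 1))
  y <- ghostForward(blk, x)
  y1 <- max(2 * 4 + (-3) * 1, 0)   # pointwise product, ReLU
  y2 <- max(0.5 * y1, 0)           # depthwise centre tap, ReLU
  expect_equal(as.vector(y), c(y1, y2), tolerance = 1e-10)
})

test_that("Ghost module with DFC matches the loop oracle on random 4x4 inputs", {
  for (seed in 1:3) {
    blk <- ghostBlock(6L, 8L, dfc = TRUE, seed = seed)
    x <- rand_fmap(4, 4, 6, 2, seed = seed + 10)
    expect_equal(ghostForward(blk, x), oracle_ghost(blk, x),
                 tolerance = 1e-5)
  }
})

test_that("DFC attention produces a sigmoid gate of the right shape", {
  blk <- ghostBlock(8L, 12L, seed = 5)
  x <- rand_fmap(16, 16, 8, 1, seed = 5)
  g <- dfcAttention(blk, x)
  expect_identical(dim(g), c(16L, 16L, 12L, 1L))
  expect_true(all(g > 0 & g < 1))
  zero_block_weights(blk)
  g0 <- dfcAttention(blk, x)
  expect_equal(as.vector(g0), rep(0.5, length(g0)))
  expect_error(dfcAttention(blk, rand_fmap(1, 1, 8, 1)), "at least 2x2")
})

test_that("disabling the DFC gate recovers the plain Ghost concatenation", {
  with_dfc <- ghostBlock(8L, 16L, dfc = TRUE, seed = 6)
  plain <- ghostBlock(8L, 16L, dfc = FALSE, seed = 99)
  for (nm in ls(plain$params))
    assign(nm, get(nm, envir = with_dfc$params), envir = plain$params)
  x <- rand_fmap(8, 8, 8, 1, seed = 6)
  gate <- dfcAttention(with_dfc, x)
  expect_equal(ghostForward(with_dfc, x), ghostForward(plain, x) * gate,
               tolerance = 1e-12)
})

test_that("strip pooling averages rows and columns", {
  # channel map [[1,2],[3,4]] (rows are height): column-major fill
  x <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))
  sp <- stripPool(x)
  expect_equal(as.vector(sp$horiz), c(1.5, 3.5))
  expect_equal(as.vector(sp$vert), c(2, 3))
  # constant map
  xc <- array(7.5, c(3, 5, 2, 1))
  spc <- stripPool(xc)
  expect_true(all(spc$horiz == 7.5) && all(spc$vert == 7.5))
  # means bounded by row/column extremes
  xr <- rand_fmap(5, 7, 3, 2, seed = 8)
  spr <- stripPool(xr)
  for (n in 1:2) for (c in 1:3) for (h in 1:5) {
    row <- xr[h, , c, n]
    expect_true(spr$horiz[h, 1, c, n] >= min(row) &&
                spr$horiz[h, 1, c, n] <= max(row))
  }
})

test_that("ELA preserves shape, attenuates, and matches the loop oracle", {
  blk <- elaBlock(32L, seed = 7)
  x <- rand_fmap(16, 16, 32, 1, seed = 7)
  y <- elaForward(blk, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))       # gates live in (0, 1)
  blk2 <- elaBlock(16L, seed = 8)
  x2 <- rand_fmap(4, 4, 16, 2, seed = 8)
  expect_equal(elaForward(blk2, x2), oracle_ela(blk2, x2), tolerance = 1e-5)
  expect_error(elaBlock(24L), "divisible")
})

test_that("attention gate weighs the skip with a per-patch sigmoid", {
  blk <- attentionGateBlock(64L, 128L, seed = 9)
  skip <- rand_fmap(32, 32, 64, 1, seed = 9)
  gating <- rand_fmap(32, 32, 128, 1, seed = 10)
  y <- attentionGateForward(blk, skip, gating)
  expect_identical(dim(y), dim(skip))
  w <- y / skip
  expect_true(all(w > 0 & w < 1))
  # one scalar weight per patch, broadcast over channels
  expect_true(max(abs(sweep(w, c(1, 2, 4), w[, , 1, , drop = FALSE]))) < 1e-9)
  zero_block_weights(blk)
  y0 <- attentionGateForward(blk, skip, gating)
  expect_equal(y0, 0.5 * skip, tolerance = 1e-12)
  expect_error(attentionGateForward(blk, skip, rand_fmap(16, 16, 128, 1)),
               "spatial")
})

test_that("every block preserves spatial size, including odd sizes", {
  for (s in c(8L, 16L, 17L, 31L)) {
    x <- rand_fmap(s, s, 16, 1, seed = s)
    spp <- sppInceptionBlock(16L, 16L, seed = s)
    expect_identical(dim(sppInceptionForward(spp, x))[1:2], c(s, s))
    gh <- ghostBlock(16L, 16L, dfc = TRUE, seed = s)
    expect_identical(dim(ghostForward(gh, x))[1:2], c(s, s))
    ela <- elaBlock(16L, seed = s)
    expect_identical(dim(elaForward(ela, x))[1:2], c(s, s))
    gt <- attentionGateBlock(16L, 32L, seed = s)
    y <- attentionGateForward(gt, x, rand_fmap(s, s, 32, 1, seed = s + 1))
    expect_identical(dim(y)[1:2], c(s, s))
    # rectangular as well
    x2 <- rand_fmap(s, 8L, 16, 1, seed = s + 2)
    expect_identical(dim(ghostForward(gh, x2))[1:2], c(s, 8L))
  }
})

test_that("all sigmoid-derived gates stay strictly inside (0, 1)", {
  x <- rand_fmap(8, 8, 16, 2, seed = 42) * 5
  gh <- ghostBlock(16L, 16L, seed = 1)
  expect_true(all(dfcAttention(gh, x) > 0 & dfcAttention(gh, x) < 1))
  ela <- elaBlock(16L, seed = 1)
  y <- elaForward(ela, x)
  ratio <- abs(y / x)
  expect_true(all(ratio > 0 & ratio < 1))
})
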
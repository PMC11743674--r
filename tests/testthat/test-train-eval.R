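test_that("BCE-with-logits matches its closed forms", {
  expect_equal(bceWithLogitsLoss(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bceWithLogitsLoss(array(0, c(3, 3)), array(0, c(3, 3))),
               log(2), tolerance = 1e-12)
  # saturated logits
  y <- array(c(1, 0, 1, 0), c(2, 2))
  x <- array(c(40, -40, 40, -40), c(2, 2))
  expect_lt(bceWithLogitsLoss(x, y), 1e-10)
  # agrees with the naive sigmoid/log evaluation at moderate logits
  set.seed(41)
  x <- array(runif(64, -5, 5), c(8, 8))
  y <- array(rbinom(64, 1, 0.5), c(8, 8))
  expect_equal(bceWithLogitsLoss(x, y), oracle_bce(x, y), tolerance = 1e-10)
  expect_true(is.finite(bceWithLogitsLoss(array(1e4, c(2, 2)),
                                          array(0, c(2, 2)))))
  expect_error(bceWithLogitsLoss(c(1, 2), c(1, 2, 3)), "differ")
})

test_that("confusion metrics match hand counts and the oracle tally", {
  # 2x2: prediction = top row, truth = left column
  m <- confusionMetrics(tp = 1, fp = 1, tn = 1, fn = 1)
  expect_equal(unname(m[c("dsc", "iou", "acc", "sen", "spe")]),
               c(0.5, 1 / 3, 0.5, 0.5, 0.5))
  # identity prediction
  mi <- confusionMetrics(tp = 7, fp = 0, tn = 9, fn = 0)
  expect_equal(unname(mi[c("dsc", "iou", "acc")]), c(1, 1, 1))
  # empty-class conventions
  expect_equal(confusionMetrics(0, 0, 4, 0)[["dsc"]], 1)   # both empty
  expect_equal(confusionMetrics(0, 2, 2, 0)[["dsc"]], 0)   # spurious fg
  expect_equal(confusionMetrics(0, 0, 4, 0)[["sen"]], 1)
  # random masks against the loop tally
  set.seed(42)
  for (rep in 1:5) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    truth <- matrix(rbinom(256, 1, 0.5), 16, 16)
    o <- oracle_metrics(pred, truth)
    m <- confusionMetrics(o["tp"], o["fp"], o["tn"], o["fn"])
    expect_equal(unname(m["dsc"]),
                 unname(2 * o["tp"] / (2 * o["tp"] + o["fp"] + o["fn"])))
    expect_equal(unname(m["acc"]), unname((o["tp"] + o["tn"]) / 256))
  }
})

test_that("evaluation pools confusion counts and keeps the DSC/IoU identity", {
  net <- buildMSGUNet(seed = 8)
  ds <- generateSynthetic(synthConfig(nSamples = 4, imageSize = 32, seed = 8))
  rep <- evaluateNetwork(net, ds)
  per <- rep@perImage
  expect_equal(sum(rep@counts), 4 * 32 * 32)           # every pixel counted
  # DSC = 2 IoU / (1 + IoU) per image, hence dsc >= iou
  expect_equal(per$dsc, 2 * per$iou / (1 + per$iou), tolerance = 1e-12)
  expect_true(all(per$dsc >= per$iou))
  v <- metricValues(rep)
  expect_true(all(v >= 0 & v <= 1))
  # order invariance
  rep2 <- evaluateNetwork(net, rev(ds))
  expect_equal(sort(rep2@perImage$dsc), sort(per$dsc))
  expect_equal(metricValues(rep2), v)
  # against the per-pixel oracle on one image
  logits <- netForward(net, get("stack_batch",
                                asNamespace("msgunet"))(ds[1])$x)
  pred <- (1 / (1 + exp(-logits[, , 1, 1]))) >= 0.5
  o <- oracle_metrics(pred * 1, ds[[1]]$mask)
  expect_equal(as.numeric(per[1, c("tp", "fp", "tn", "fn")]),
               as.numeric(o[c("tp", "fp", "tn", "fn")]))
})

test_that("a perfect prediction scores 1 everywhere", {
  # force logits to reproduce the mask: zero net + bias through the head is
  # constant, so instead score the mask against itself via confusion counts
  msk <- matrix(rbinom(64, 1, 0.5), 8, 8)
  o <- oracle_metrics(msk, msk)
  m <- confusionMetrics(o["tp"], o["fp"], o["tn"], o["fn"])
  expect_equal(unname(m[c("dsc", "iou", "acc", "sen", "spe")]),
               rep(1, 5))
})

test_that("training records history, is seeded, and decreases the loss", {
  ds <- generateSynthetic(synthConfig(nSamples = 4, imageSize = 32, seed = 2))
  cfg <- trainConfig(epochs = 3, batchSize = 4, seed = 7, augment = FALSE)
  r1 <- trainNetwork(buildMSGUNet(seed = 7), ds, cfg)
  expect_identical(nrow(r1$history), 3L)               # one row per epoch
  expect_identical(r1$history$epoch, 1:3)
  r2 <- trainNetwork(buildMSGUNet(seed = 7), ds, cfg)
  expect_identical(r1$history$loss, r2$history$loss)   # same seed, same run
  expect_lt(r1$history$loss[3], r1$history$loss[1])
  expect_error(trainNetwork(buildMSGUNet(seed = 1), list(), cfg), "no training")
})

test_that("the plateau scheduler decays towards the floor learning rate", {
  cfgs <- trainConfig(lrInit = 1e-3, lrMin = 1e-5, schedPatience = 1L)
  expect_identical(cfgs$schedPatience, 1L)
  ds <- generateSynthetic(synthConfig(nSamples = 2, imageSize = 32, seed = 3))
  # a zero learning-rate-friendly setup: loss cannot improve when lrInit is 0?
  # instead: patience 0 would decay every epoch; with patience 1 and a tiny
  # run the lr column must be non-increasing and bounded below by lrMin
  cfg <- trainConfig(epochs = 4, batchSize = 2, seed = 3, augment = FALSE,
                     lrInit = 1e-4, lrMin = 1e-5, schedPatience = 1L)
  r <- trainNetwork(buildMSGUNet(seed = 3), ds, cfg)
  expect_true(all(diff(r$history$lr) <= 0))
  expect_true(all(r$history$lr >= 1e-5))
})
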
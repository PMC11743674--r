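# Training recipe and evaluation metrics.
#
# Loss: binary cross-entropy on logits in the numerically stable
# log-sum-exp form.  Optimizer: Adam.  Scheduler: reduce-on-plateau
# (factor 0.1, patience 10 epochs, relative improvement threshold 1e-4)
# down to a floor learning rate.  Metrics are confusion-count based and
# aggregated per image.

#' Training configuration
#'
#' @param batchSize images per optimisation step (default 8).
#' @param lrInit initial Adam learning rate (default 1e-4).
#' @param lrMin floor learning rate for the plateau scheduler (default 1e-5).
#' @param epochs training epochs (default 100).
#' @param threshold probability threshold for binarising predictions.
#' @param seed seed controlling shuffling and augmentation.
#' @param schedFactor multiplicative learning-rate decay on plateau.
#' @param schedPatience epochs without improvement before decaying.
#' @param augment apply random flips / right-angle rotations each epoch.
#' @return a list of class \code{msgu_train_config}.
#' @export
trainConfig <- function(batchSize = 8L, lrInit = 1e-4, lrMin = 1e-5,
                        epochs = 100L, threshold = 0.5, seed = 1L,
                        schedFactor = 0.1, schedPatience = 10L,
                        augment = TRUE) {
  stopifnot(batchSize >= 1, lrMin <= lrInit, threshold > 0, threshold < 1,
            epochs >= 1)
  structure(list(batchSize = as.integer(batchSize), lrInit = lrInit,
                 lrMin = lrMin, epochs = as.integer(epochs),
                 threshold = threshold, seed = as.integer(seed),
                 schedFactor = schedFactor,
                 schedPatience = as.integer(schedPatience),
                 augment = isTRUE(augment)),
            class = "msgu_train_config")
}

#' Binary cross-entropy with logits
#'
#' Mean binary cross-entropy computed directly on logits with the
#' log-sum-exp formulation \code{max(x, 0) - x * y + log(1 + exp(-|x|))},
#' finite for any finite logits.
#'
#' @param logits numeric array of raw scores.
#' @param target array of the same shape with values in [0, 1].
#' @return scalar loss.
#' @examples
#' bceWithLogitsLoss(0, 1)  # log(2)
#' @export
bceWithLogitsLoss <- function(logits, target) {
  if (length(logits) != length(target))
    stop("logits and target sizes differ")
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

# stack a list of samples into input (H,W,3,B) and target (H,W,1,B) arrays
stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  b <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], b))
  y <- array(0, c(d[1], d[2], 1, b))
  for (i in seq_len(b)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list()
  st$v <- list()
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]
    v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    old <- get(nm, envir = params, inherits = FALSE)
    assign(nm, old - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = params)
  }
  invisible(NULL)
}

# One optimisation step: forward with a tape, backward, Adam update.
# Returns the loss value.
train_step <- function(net, x, y, st, lr) {
  ctx <- ag_ctx()
  leaves <- new.env(parent = emptyenv())
  nms <- ls(net@params, all.names = TRUE)
  for (nm in nms)
    assign(nm, ag_leaf(ctx, get(nm, envir = net@params, inherits = FALSE)),
           envir = leaves)
  logits <- net_forward_impl(net, x, ctx = ctx, training = TRUE,
                             leaves = leaves)
  loss <- ag_bce_logits(ctx, logits, y)
  lv <- loss$value
  ag_backward(ctx, loss)
  grads <- lapply(structure(nms, names = nms), function(nm)
    get(nm, envir = leaves, inherits = FALSE)$grad)
  adam_step(net@params, grads, st, lr)
  lv
}

#' Train a segmentation network
#'
#' Adam on BCE-with-logits with per-epoch shuffling, optional geometric
#' augmentation and a reduce-on-plateau learning-rate schedule.  The network
#' is updated in place (its parameters live in an environment) and also
#' returned.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param samples list of segmentation samples (see
#'   \code{\link{generateSynthetic}} / \code{\link{loadISICDir}}); all images
#'   must share one size, divisible by 16.
#' @param config a \code{\link{trainConfig}}.
#' @param valSamples optional validation samples; when given, the scheduler
#'   monitors validation loss, otherwise training loss.
#' @param verbose print one line per epoch.
#' @return list with \code{net} and \code{history}, a data.frame with one row
#'   per epoch (loss, validation loss where available, learning rate).
#' @export
trainNetwork <- function(net, samples, config = trainConfig(),
                         valSamples = NULL, verbose = FALSE) {
  if (length(samples) == 0) stop("no training samples")
  lr <- config$lrInit
  st <- adam_state()
  best <- Inf
  wait <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     valLoss = numeric(), lr = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(child_seed(config$seed, ep),
                     sample.int(length(samples)))
    losses <- numeric()
    for (start in seq(1, length(ord), by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, length(ord))]
      batch <- samples[idx]
      if (config$augment)
        batch <- lapply(seq_along(batch), function(k)
          augmentSample(batch[[k]],
                        seed = child_seed(config$seed, ep * 10000L + idx[k])))
      b <- stack_batch(batch)
      losses <- c(losses, train_step(net, b$x, b$y, st, lr))
    }
    epoch_loss <- mean(losses)
    val_loss <- NA_real_
    if (!is.null(valSamples)) {
      vb <- stack_batch(valSamples)
      val_loss <- bceWithLogitsLoss(
        net_forward_impl(net, vb$x, training = FALSE), vb$y)
    }
    monitor <- if (is.na(val_loss)) epoch_loss else val_loss
    if (monitor < best * (1 - 1e-4)) {
      best <- monitor
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$schedPatience && lr > config$lrMin) {
        lr <- max(lr * config$schedFactor, config$lrMin)
        wait <- 0L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = epoch_loss,
                                   valLoss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  lr %.2e", ep, epoch_loss, lr))
  }
  list(net = net, history = hist)
}

## ---- metrics ----

#' Metrics from confusion counts
#'
#' @param tp,fp,tn,fn pixel counts.
#' @return named vector: dsc, iou (foreground), iouBg, acc, sen, spe.
#'   Degenerate denominators follow the all-empty convention: a class absent
#'   from both prediction and truth scores 1, absent from only one scores 0.
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  safe <- function(num, den, empty) if (den == 0) (if (empty) 1 else 0)
                                    else num / den
  c(dsc = safe(2 * tp, 2 * tp + fp + fn, tp + fp + fn == 0),
    iou = safe(tp, tp + fp + fn, tp + fp + fn == 0),
    iouBg = safe(tn, tn + fp + fn, tn + fp + fn == 0),
    acc = (tp + tn) / (tp + fp + tn + fn),
    sen = safe(tp, tp + fn, tp + fn == 0),
    spe = safe(tn, tn + fp, tn + fp == 0))
}

#' Evaluate a network on labelled samples
#'
#' Predictions are \code{sigmoid(logits) >= threshold}; confusion counts are
#' tallied per image and pooled.  Headline metrics are per-image means; the
#' foreground IoU mean is reported as \code{miou} (the comparison-literature
#' convention) with the two-class mean alongside.
#'
#' @param net a \linkS4class{SegNetwork}.
#' @param samples list of segmentation samples.
#' @param threshold binarisation threshold in (0, 1).
#' @param batchSize forward-pass batch size.
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateNetwork <- function(net, samples, threshold = 0.5, batchSize = 8L) {
  if (length(samples) == 0) stop("no samples to evaluate")
  stopifnot(threshold > 0, threshold < 1)
  rows <- vector("list", length(samples))
  k <- 0L
  for (start in seq(1, length(samples), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(samples))
    b <- stack_batch(samples[idx])
    logits <- net_forward_impl(net, b$x, training = FALSE)
    prob <- 1 / (1 + exp(-logits))
    pred <- prob >= threshold
    for (j in seq_along(idx)) {
      p <- pred[, , 1, j]
      t <- b$y[, , 1, j] > 0.5
      tp <- sum(p & t); fp <- sum(p & !t)
      fn <- sum(!p & t); tn <- sum(!p & !t)
      m <- confusionMetrics(tp, fp, tn, fn)
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = samples[[idx[j]]]$id %||% as.character(idx[j]),
        tp = tp, fp = fp, tn = tn, fn = fn,
        dsc = m["dsc"], iou = m["iou"], iouBg = m["iouBg"],
        acc = m["acc"], sen = m["sen"], spe = m["spe"],
        row.names = NULL)
    }
  }
  per <- do.call(rbind, rows)
  counts <- c(tp = sum(per$tp), fp = sum(per$fp), tn = sum(per$tn),
              fn = sum(per$fn))
  new("MetricsReport", counts = counts, perImage = per,
      dsc = mean(per$dsc), miou = mean(per$iou),
      miouTwoClass = mean((per$iou + per$iouBg) / 2),
      acc = mean(per$acc), sen = mean(per$sen), spe = mean(per$spe),
      threshold = threshold)
}
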
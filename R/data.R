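# Data handling: ISIC-style directory loading, train/test splitting,
# geometric augmentation, and a fully seeded synthetic dermoscopy generator
# (skin-toned background, one darker irregular elliptical lesion with a
# pixel-exact mask, optional hair-strand occluders, Gaussian noise).
#
# A segmentation sample is a list with `image` (H x W x 3 array on [0, 1]),
# `mask` (H x W array with values in {0, 1}) and `id` (character).

#' Construct a segmentation sample
#'
#' @param image H x W x 3 numeric array with values in [0, 1].
#' @param mask H x W numeric/logical array; coerced to 0/1.
#' @param id sample identifier.
#' @return a list of class \code{SegSample}.
#' @export
segSample <- function(image, mask, id = "sample") {
  mask <- (mask > 0.5) * 1
  dim(mask) <- dim(mask)[1:2]
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask sizes differ")
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be H x W x 3")
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "SegSample")
}

# EBImage stores (x = width, y = height[, channel]); internal layout is
# (H, W[, C]).
ebi_to_hwc <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L))
}

hwc_to_ebi <- function(a) {
  if (length(dim(a)) == 2L)
    EBImage::Image(t(a), colormode = "Grayscale")
  else
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
}

#' Load an ISIC-style dataset directory
#'
#' Expects \code{images/<id>.<ext>} and \code{masks/<id><maskSuffix>.png}
#' (the ISIC convention is \code{_segmentation}).  Images are resized
#' bilinearly, masks with nearest-neighbour and re-binarised at 0.5 so they
#' stay exactly \{0, 1\}.  Samples are returned in lexicographic id order;
#' unmatched files are skipped with a warning.
#'
#' @param root dataset directory.
#' @param imageSize target square size in pixels.
#' @param imagesDir,masksDir subdirectory names.
#' @param maskSuffix suffix between the id and the mask extension.
#' @return list of \code{SegSample}.
#' @export
loadISICDir <- function(root, imageSize = 256L, imagesDir = "images",
                        masksDir = "masks", maskSuffix = "_segmentation") {
  ipath <- file.path(root, imagesDir)
  mpath <- file.path(root, masksDir)
  if (!dir.exists(ipath)) stop("no image directory at ", ipath)
  files <- list.files(ipath, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no images found in ", ipath)
  ids <- sub("\\.[^.]+$", "", files)
  ord <- order(ids, method = "radix")
  files <- files[ord]; ids <- ids[ord]
  out <- list()
  skipped <- 0L
  for (k in seq_along(files)) {
    mfile <- file.path(mpath, paste0(ids[k], maskSuffix, ".png"))
    if (!file.exists(mfile)) { skipped <- skipped + 1L; next }
    img <- EBImage::resize(EBImage::readImage(file.path(ipath, files[k])),
                           w = imageSize, h = imageSize)
    msk <- EBImage::resize(EBImage::readImage(mfile),
                           w = imageSize, h = imageSize, filter = "none")
    ma <- EBImage::imageData(msk)
    if (length(dim(ma)) == 3L) ma <- ma[, , 1L]
    out[[length(out) + 1L]] <- segSample(ebi_to_hwc(img), t(ma) > 0.5, ids[k])
  }
  if (skipped > 0)
    warning(skipped, " image(s) without a matching mask were skipped")
  if (length(out) == 0) stop("no matched image/mask pairs under ", root)
  out
}

#' Write samples as an ISIC-style directory tree
#'
#' @param samples list of \code{SegSample}.
#' @param dir output directory; \code{images/} and \code{masks/} are created.
#' @param overwrite allow writing into a non-empty directory.
#' @return \code{dir}, invisibly.
#' @export
writeSegSamples <- function(samples, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory ", dir, " is not empty (use overwrite)")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    EBImage::writeImage(hwc_to_ebi(s$image),
                        file.path(dir, "images", paste0(s$id, ".png")))
    EBImage::writeImage(hwc_to_ebi(s$mask),
                        file.path(dir, "masks",
                                  paste0(s$id, "_segmentation.png")))
  }
  invisible(dir)
}

#' Seeded train/test split
#'
#' Shuffles with the given seed and splits at \code{floor(ratio * n)}; the
#' two parts are disjoint and exhaustive.
#'
#' @param samples list of samples.
#' @param ratio training fraction in (0, 1); the reference recipe uses 0.7.
#' @param seed shuffle seed.
#' @return list with \code{train} and \code{test}.
#' @export
splitTrainTest <- function(samples, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(samples)
  ord <- with_seed(seed, sample.int(n))
  ntr <- floor(ratio * n)
  list(train = samples[ord[seq_len(ntr)]],
       test = samples[ord[setdiff(seq_len(n), seq_len(ntr))]])
}

#' Split by a manifest of sample ids
#'
#' Honors a fixed, published train/test partition instead of the seeded
#' ratio split: the manifest is a JSON file (or list) with character vectors
#' \code{train} and \code{test} of sample ids.
#'
#' @param samples list of samples.
#' @param manifest path to a JSON manifest, or a list with \code{train} and
#'   \code{test} id vectors.
#' @return list with \code{train} and \code{test}; ids missing from the
#'   samples are an error, samples missing from the manifest are dropped
#'   with a warning.
#' @export
splitByManifest <- function(samples, manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (is.null(manifest$train) || is.null(manifest$test))
    stop("manifest must contain 'train' and 'test' id vectors")
  ids <- vapply(samples, `[[`, "", "id")
  missing <- setdiff(c(manifest$train, manifest$test), ids)
  if (length(missing))
    stop("manifest ids not present in the samples: ",
         paste(utils::head(missing, 5), collapse = ", "))
  unused <- setdiff(ids, c(manifest$train, manifest$test))
  if (length(unused))
    warning(length(unused), " sample(s) not named in the manifest were dropped")
  list(train = samples[match(manifest$train, ids)],
       test = samples[match(manifest$test, ids)])
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot_image <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  if (length(dim(a)) == 2L) {
    for (i in seq_len(k)) a <- rot90cw(a)
    return(a)
  }
  out <- NULL
  for (c in seq_len(dim(a)[3L])) {
    m <- a[, , c]
    for (i in seq_len(k)) m <- rot90cw(m)
    if (is.null(out)) out <- array(0, c(dim(m), dim(a)[3L]))
    out[, , c] <- m
  }
  out
}

flip_image <- function(a, horizontal) {
  if (horizontal) {
    if (length(dim(a)) == 2L) a[, ncol(a):1] else a[, dim(a)[2L]:1, , drop = FALSE]
  } else {
    if (length(dim(a)) == 2L) a[nrow(a):1, ] else a[dim(a)[1L]:1, , , drop = FALSE]
  }
}

#' Random geometric augmentation
#'
#' Horizontal and vertical flips (each with probability 0.5) and rotation by
#' a uniformly drawn multiple of 90 degrees.  Image and mask receive the
#' identical transform, so the pair stays co-registered and the mask stays
#' exactly binary (no interpolation).
#'
#' @param sample a \code{SegSample}.
#' @param seed seed for the draw; equal seeds give equal transforms.
#' @return the augmented \code{SegSample}.
#' @export
augmentSample <- function(sample, seed = 1L) {
  draws <- with_seed(seed, c(stats::runif(2), sample.int(4L, 1L) - 1L))
  img <- sample$image
  msk <- sample$mask
  if (draws[1] < 0.5) { img <- flip_image(img, TRUE); msk <- flip_image(msk, TRUE) }
  if (draws[2] < 0.5) { img <- flip_image(img, FALSE); msk <- flip_image(msk, FALSE) }
  k <- as.integer(draws[3])
  img <- rot_image(img, k)
  msk <- rot_image(msk, k)
  segSample(img, msk, sample$id)
}

## ---- synthetic dermoscopy generator ----

# One sample; runs inside a seeded RNG context.
synth_one <- function(size, areaRange, hairProb, noiseSd, id) {
  hh <- matrix(seq(0, 1, length.out = size), size, size)
  ww <- t(hh)

  # skin-toned background with a low-frequency colour field
  base <- c(0.86, 0.67, 0.55) * stats::runif(1, 0.92, 1.04)
  field <- matrix(0, size, size)
  for (k in 1:3)
    field <- field + stats::runif(1, -1, 1) *
      cos(2 * pi * (stats::runif(1, 0.3, 1.2) * hh +
                    stats::runif(1, 0.3, 1.2) * ww) +
          stats::runif(1, 0, 2 * pi))
  field <- field / 3
  img <- array(0, c(size, size, 3))
  for (c in 1:3)
    img[, , c] <- base[c] * (1 + 0.05 * field * stats::runif(1, 0.7, 1.3))

  # irregular elliptical lesion: star-shaped boundary (low radial harmonics,
  # bounded amplitude), rescaled until the mask area lands in the target range
  target <- stats::runif(1, areaRange[1], areaRange[2])
  cy <- stats::runif(1, 0.38, 0.62) * size
  cx <- stats::runif(1, 0.38, 0.62) * size
  aspect <- stats::runif(1, 0.55, 0.95)
  theta <- stats::runif(1, 0, pi)
  nharm <- 4L
  amp <- stats::runif(nharm, -1, 1) * 0.28 / (1 + seq_len(nharm))
  phase <- stats::runif(nharm, 0, 2 * pi)
  ry <- sqrt(target * size^2 / (pi * aspect))
  rx <- ry * aspect
  dy <- matrix(seq_len(size) - cy, size, size)
  dx <- t(matrix(seq_len(size) - cx, size, size))
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  phi <- atan2(v, u)
  pert <- 1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * cos((k + 1) * phi + phase[k])))
  pert <- pmax(pert, 0.35)
  mask <- NULL
  for (it in 1:25) {
    r <- sqrt((u / ry)^2 + (v / rx)^2)
    mask <- (r <= pert) * 1
    frac <- mean(mask)
    if (frac >= areaRange[1] && frac <= areaRange[2]) break
    if (frac == 0) { ry <- ry * 2; rx <- rx * 2; next }
    s <- sqrt(target / frac)
    ry <- ry * s
    rx <- rx * s
  }
  frac <- mean(mask)
  if (frac < areaRange[1] || frac > areaRange[2])
    stop("could not realise a lesion area in [", areaRange[1], ", ",
         areaRange[2], "] at image size ", size)

  # darker interior with a mild radial texture
  shade <- stats::runif(1, 0.45, 0.62)
  rcl <- pmin(sqrt((u / ry)^2 + (v / rx)^2) / pert, 1)
  mult <- shade + 0.25 * shade * rcl^2
  inside <- mask == 1
  for (c in 1:3) {
    pl <- img[, , c]
    pl[inside] <- pl[inside] * mult[inside]
    img[, , c] <- pl
  }

  # hair strands: thin dark quadratic curves drawn over the image only
  if (stats::runif(1) < hairProb) {
    for (s in seq_len(sample.int(5L, 1L) + 1L)) {
      p0 <- stats::runif(2, 0, 1) * size
      p2 <- stats::runif(2, 0, 1) * size
      mid <- (p0 + p2) / 2 + stats::rnorm(2, sd = 0.25 * size)
      tt <- seq(0, 1, length.out = 6L * size)
      py <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * mid[1] + tt^2 * p2[1]
      px <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * mid[2] + tt^2 * p2[2]
      col <- c(0.16, 0.11, 0.08) * stats::runif(1, 0.6, 1.4)
      thick <- stats::runif(1) < 0.35
      offs <- if (thick) rbind(c(0, 0), c(1, 0), c(0, 1)) else rbind(c(0, 0))
      for (o in seq_len(nrow(offs))) {
        yy <- round(py) + offs[o, 1]
        xx <- round(px) + offs[o, 2]
        ok <- yy >= 1 & yy <= size & xx >= 1 & xx <= size
        for (c in 1:3)
          img[cbind(yy[ok], xx[ok], c)] <-
            0.15 * img[cbind(yy[ok], xx[ok], c)] + 0.85 * col[c]
      }
    }
  }

  img <- img + array(stats::rnorm(size * size * 3, sd = noiseSd),
                     c(size, size, 3))
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(size, size, 3)
  segSample(img, mask, id)
}

#' Generate synthetic dermoscopy samples
#'
#' Each sample is a skin-toned background with a seeded low-frequency colour
#' field, one darker lesion with an irregular (star-shaped, low-harmonic)
#' elliptical boundary and a pixel-exact binary mask, optional dark hair
#' strands drawn over the image only, and Gaussian pixel noise.  The lesion
#' is rescaled until its area fraction lies inside
#' \code{lesionAreaRange}, so every emitted mask satisfies the range by
#' construction.  The whole dataset is a pure function of the configuration.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list of \code{SegSample}.
#' @examples
#' ds <- generateSynthetic(synthConfig(nSamples = 2, imageSize = 64))
#' mean(ds[[1]]$mask)
#' @export
generateSynthetic <- function(config) {
  validObject(config)
  lapply(seq_len(config@nSamples), function(i)
    with_seed(child_seed(config@seed, i),
              synth_one(config@imageSize, config@lesionAreaRange,
                        config@hairProbability, config@noiseSd,
                        sprintf("synth_%04d", i))))
}
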
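make_dummy_samples <- function(n, size = 8L) {
  lapply(seq_len(n), function(i) {
    msk <- matrix(0, size, size)
    msk[2:4, 2:4] <- 1
    segSample(array(runif(size * size * 3), c(size, size, 3)), msk,
              sprintf("d%04d", i))
  })
}

test_that("ISIC-style directories round-trip through write and load", {
  dir <- file.path(tempdir(), "isic_fixture")
  unlink(dir, recursive = TRUE)
  set.seed(21)
  samples <- generateSynthetic(synthConfig(nSamples = 4, imageSize = 32,
                                           seed = 21))
  writeSegSamples(samples, dir)
  loaded <- loadISICDir(dir, imageSize = 32)
  expect_length(loaded, 4)
  expect_identical(vapply(loaded, `[[`, "", "id"),
                   sort(vapply(samples, `[[`, "", "id")))
  for (s in loaded) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_identical(dim(s$image), c(32L, 32L, 3L))
    # PNG round trip quantises to 8 bit
    expect_lt(max(abs(s$image - samples[[match(s$id, vapply(samples, `[[`,
      "", "id"))]]$image)), 1 / 255 + 1e-8)
  }
  # masks written as 0/255-style PNG come back as exact 0/1 after resizing
  resized <- loadISICDir(dir, imageSize = 16)
  expect_true(all(vapply(resized, function(s)
    all(s$mask %in% c(0, 1)), logical(1))))
})

test_that("loader reports unmatched pairs and empty directories", {
  dir <- file.path(tempdir(), "isic_bad")
  unlink(dir, recursive = TRUE)
  dir.create(file.path(dir, "images"), recursive = TRUE)
  dir.create(file.path(dir, "masks"), recursive = TRUE)
  expect_error(loadISICDir(dir), "no images")
  s <- make_dummy_samples(2)
  writeSegSamples(s, dir, overwrite = TRUE)
  file.remove(file.path(dir, "masks", "d0002_segmentation.png"))
  expect_warning(got <- loadISICDir(dir, imageSize = 8), "skipped")
  expect_length(got, 1)
})

test_that("train/test split is a seeded floor split, disjoint and exhaustive", {
  s <- make_dummy_samples(2150, size = 8L)
  sp <- splitTrainTest(s, ratio = 0.7, seed = 3)
  expect_length(sp$train, 1505)
  expect_length(sp$test, 645)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(s))
  sp2 <- splitTrainTest(s, ratio = 0.7, seed = 3)
  expect_identical(ids(sp$train), ids(sp2$train))
  half <- splitTrainTest(make_dummy_samples(10), ratio = 0.5, seed = 1)
  expect_length(half$train, 5)
  expect_error(splitTrainTest(s, ratio = 0), "ratio")
})

test_that("a manifest file pins an exact published partition", {
  s <- make_dummy_samples(6)
  man <- list(train = c("d0002", "d0005", "d0001"), test = c("d0004", "d0006"))
  expect_warning(sp <- splitByManifest(s, man), "dropped")   # d0003 unused
  expect_identical(vapply(sp$train, `[[`, "", "id"), man$train)
  expect_identical(vapply(sp$test, `[[`, "", "id"), man$test)
  path <- file.path(tempdir(), "manifest.json")
  jsonlite::write_json(man, path)
  expect_warning(sp2 <- splitByManifest(s, path), "dropped")
  expect_identical(vapply(sp2$train, `[[`, "", "id"), man$train)
  expect_error(splitByManifest(s, list(train = "nope", test = "d0001")),
               "not present")
})

test_that("augmentation keeps image and mask co-registered and binary", {
  ns <- asNamespace("msgunet")
  flip <- get("flip_image", ns)
  m <- matrix(runif(64), 8, 8)
  expect_identical(flip(flip(m, TRUE), TRUE), m)       # flips are involutions
  expect_identical(flip(flip(m, FALSE), FALSE), m)
  expect_identical(get("rot_image", ns)(m, 0L), m)     # 0 degrees = identity
  set.seed(31)
  base <- generateSynthetic(synthConfig(nSamples = 1, imageSize = 32,
                                        seed = 31))[[1]]
  # stamp the mask into the red channel so co-registration is visible
  probe <- base
  probe$image[, , 1] <- base$mask
  for (seed in 1:12) {
    a <- augmentSample(probe, seed = seed)
    expect_identical(a$image[, , 1], a$mask * 1)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_identical(sum(a$mask), sum(probe$mask))     # bijective pixel map
  }
  expect_identical(augmentSample(probe, seed = 7)$mask,
                   augmentSample(probe, seed = 7)$mask)
})

test_that("the synthetic generator is bit-reproducible from its seed", {
  cfg <- synthConfig(nSamples = 3, imageSize = 48, seed = 99)
  a <- generateSynthetic(cfg)
  b <- generateSynthetic(cfg)
  expect_identical(a, b)
  c <- generateSynthetic(synthConfig(nSamples = 3, imageSize = 48, seed = 100))
  expect_false(identical(a, c))
})

test_that("synthetic lesions respect area bounds, contrast and connectivity", {
  cfg <- synthConfig(nSamples = 30, imageSize = 64, seed = 5,
                     hairProbability = 0.5)
  ds <- generateSynthetic(cfg)
  fracs <- vapply(ds, function(s) mean(s$mask), numeric(1))
  expect_true(all(fracs >= 0.05 & fracs <= 0.45))
  darker <- vapply(ds, function(s) {
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    mean(lum[s$mask == 1]) < mean(lum[s$mask == 0])
  }, logical(1))
  expect_true(all(darker))
  simply_connected <- vapply(ds, function(s) {
    fg <- EBImage::bwlabel(s$mask)
    bg <- EBImage::bwlabel(1 - s$mask)
    max(fg) == 1 && max(bg) == 1
  }, logical(1))
  expect_gte(mean(simply_connected), 0.95)
  for (s in ds) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_identical(dim(s$image)[1:2], dim(s$mask))
  }
})

test_that("infeasible lesion-area ranges are rejected", {
  expect_error(synthConfig(lesionAreaRange = c(0.5, 0.95)), "0.9")
  expect_error(generateSynthetic(
    synthConfig(nSamples = 1, imageSize = 16,
                lesionAreaRange = c(0.001, 0.002), seed = 1)),
    "lesion area|could not realise")
})
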
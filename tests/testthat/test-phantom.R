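test_that("phantom generation is a pure function of its spec", {
  sp <- phantomSpec(height = 64L, width = 64L, seed = 7L)
  expect_identical(imageData(makePhantom(sp)), imageData(makePhantom(sp)))
  sp2 <- sp; sp2$seed <- 8L
  expect_false(identical(imageData(makePhantom(sp)), imageData(makePhantom(sp2))))
})

test_that("degenerate spec gives exactly background plus one ellipse level", {
  im <- makePhantom(phantomSpec(nEllipses = 1L, textureAmplitude = 0,
                                seed = 3L))
  expect_length(unique(as.vector(imageData(im))), 2L)
})

test_that("pixel histogram matches an independently regenerated phantom", {
  sp <- phantomSpec(height = 64L, width = 64L, nEllipses = 5L, seed = 1L)
  h1 <- hist(imageData(makePhantom(sp)), breaks = seq(0, 1, by = 0.05),
             plot = FALSE)$counts
  h2 <- hist(imageData(makePhantom(phantomSpec(height = 64L, width = 64L,
                                               nEllipses = 5L, seed = 1L))),
             breaks = seq(0, 1, by = 0.05), plot = FALSE)$counts
  expect_identical(h1, h2)
  expect_equal(sum(h1), 64 * 64)
})

test_that("phantom values respect the declared intensity range and size", {
  sp <- phantomSpec(height = 48L, width = 32L, intensityRange = c(0, 2),
                    seed = 5L)
  im <- makePhantom(sp)
  expect_identical(dim(imageData(im)), c(48L, 32L))
  expect_true(all(imageData(im) >= 0 & imageData(im) <= 2))
  expect_error(phantomSpec(height = 4L), "invalid spec")
  expect_error(phantomSpec(nEllipses = 0L), "invalid spec")
  expect_error(phantomSpec(textureAmplitude = 1.5), "invalid spec")
})

test_that("identity-configured augmentation is the pixel-exact identity", {
  im <- smallPhantom(2L)
  id <- augmentSpec(flipLr = FALSE, rotateDegMax = 0, shiftFrac = 0,
                    zoomRange = c(1, 1), brightnessJitter = 0,
                    elasticAlpha = 0, seed = 11L)
  expect_identical(imageData(augmentImage(im, id)), imageData(im))
})

test_that("a forced flip applied twice restores the original", {
  im <- smallPhantom(4L)
  # find a seed whose draw actually flips, then apply the same transform twice
  flipped <- NULL
  for (s in 1:25) {
    sp <- augmentSpec(flipLr = TRUE, rotateDegMax = 0, shiftFrac = 0,
                      zoomRange = c(1, 1), brightnessJitter = 0,
                      elasticAlpha = 0, seed = s)
    out <- augmentImage(im, sp)
    if (!identical(imageData(out), imageData(im))) { flipped <- sp; break }
  }
  expect_false(is.null(flipped))
  twice <- augmentImage(augmentImage(im, flipped), flipped)
  expect_identical(imageData(twice), imageData(im))
})

test_that("a +20 degree rotation matches an independent resampler", {
  im <- imageData(smallPhantom(6L))
  expect_equal(warpImage(im, angleDeg = 20), naiveRotate(im, 20),
               tolerance = 1e-12)
})

test_that("augmentation draws are deterministic per seed and clipped", {
  im <- smallPhantom(8L)
  sp <- augmentSpec(seed = 21L)
  a1 <- augmentImage(im, sp); a2 <- augmentImage(im, sp)
  expect_identical(imageData(a1), imageData(a2))
  expect_true(all(imageData(a1) >= 0 & imageData(a1) <= 1))
  expect_identical(dim(imageData(a1)), dim(imageData(im)))
})

test_that("AWGN hits the target SNR exactly and is seed-deterministic", {
  im <- makePhantom(phantomSpec(height = 64L, width = 64L, seed = 10L))
  expect_identical(addAwgn(im, Inf, 1L), im)
  for (s in 1:20) {
    noisy <- addAwgn(im, 30, seed = s)
    noise <- imageData(noisy) - imageData(im)
    snr <- 10 * log10(mean(imageData(im)^2) / mean(noise^2))
    expect_lt(abs(snr - 30), 0.5)
  }
  expect_identical(imageData(addAwgn(im, 40, 3L)), imageData(addAwgn(im, 40, 3L)))
  zero <- MRImage(matrix(0, 16, 16))
  expect_error(addAwgn(zero, 30, 1L), "zero signal power")
})

test_that("dataset splits are sized, disjoint and regenerable", {
  sp <- phantomSpec(height = 32L, width = 32L, seed = 42L)
  ds <- makeDataset(6, 3, 3, sp, augmentSpec(seed = 1L))
  expect_length(ds$train, 6L)
  expect_length(ds$val, 3L)
  expect_length(ds$test, 3L)
  all_imgs <- lapply(c(ds$train, ds$val, ds$test), imageData)
  expect_equal(anyDuplicated(all_imgs), 0L)
  ds2 <- makeDataset(6, 3, 3, sp, augmentSpec(seed = 1L))
  expect_identical(lapply(ds$train, imageData), lapply(ds2$train, imageData))
  expect_identical(lapply(ds$test, imageData), lapply(ds2$test, imageData))
  expect_equal(nrow(ds$manifest), 12L)
})
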
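test_that("the centered transform is orthonormal: round trip and Parseval", {
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(runif(32 * 32), 32)
    k <- forwardTransform(x)
    expect_lt(max(abs(imageData(inverseTransform(k)) - x)) / max(abs(x)), 1e-6)
    expect_lt(abs(sum(x^2) - sum(Mod(kspaceData(k))^2)) / sum(x^2), 1e-6)
  }
})

test_that("a constant image concentrates all energy in the centered DC bin", {
  k <- kspaceData(forwardTransform(matrix(2.5, 16, 16)))
  dc <- c(floor(16 / 2) + 1, floor(16 / 2) + 1)
  expect_equal(Mod(k[dc[1], dc[2]]), 2.5 * sqrt(16 * 16), tolerance = 1e-9)
  off <- Mod(k); off[dc[1], dc[2]] <- 0
  expect_lt(max(off), 1e-9)
})

test_that("a lone DC bin inverts to a constant image", {
  k <- matrix(complex(real = 0), 16, 16)
  k[9, 9] <- 3 * sqrt(16 * 16)
  expect_equal(imageData(inverseTransform(KSpaceGrid(k))),
               matrix(3, 16, 16), tolerance = 1e-9)
})

test_that("masked zero-filled reconstruction matches a quadratic-cost DFT oracle", {
  x <- imageData(smallPhantom(3L, 16L))
  mask <- makeMask("gaussian1d", 16, 0.4, seed = 2)
  pkg <- imageData(zeroFilledRecon(MRImage(x), mask))
  ref <- naiveCenteredIdftMag(naiveCenteredDft(x) * maskEntries(mask))
  expect_equal(pkg, ref, tolerance = 1e-8)
})

test_that("masks retain the exact budget for every pattern, rate and size", {
  for (size in c(64L, 128L, 256L)) {
    for (rate in c(0.1, 0.2, 0.3)) {
      m1 <- makeMask("gaussian1d", size, rate, seed = 1)
      expect_equal(sum(rowSums(maskEntries(m1)) > 0), round(rate * size))
      kept <- rowSums(maskEntries(m1))
      expect_true(all(kept %in% c(0, size)))  # whole phase-encode lines
      m2 <- makeMask("gaussian2d", size, rate, seed = 1)
      expect_equal(sum(maskEntries(m2)), round(rate * size * size))
    }
  }
})

test_that("the always-retained center block is present and rates can be infeasible", {
  m <- makeMask("gaussian1d", 256, 0.1, seed = 9)
  ci <- floor(256 / 2) + 1
  expect_true(all(maskEntries(m)[(ci - 4):(ci + 5), ] == 1))
  m2 <- makeMask("gaussian2d", 64, 0.1, seed = 9)
  cj <- floor(64 / 2) + 1
  expect_true(all(maskEntries(m2)[(cj - 3):(cj + 4), (cj - 3):(cj + 4)] == 1))
  expect_error(makeMask("gaussian2d", 16, 0.1, seed = 1), "infeasible")
  expect_error(makeMask("gaussian1d", 64, 1.2, seed = 1), "between 0 and 1")
})

test_that("masks are deterministic per seed and density peaks centrally", {
  expect_identical(maskEntries(makeMask("gaussian1d", 64, 0.2, seed = 5)),
                   maskEntries(makeMask("gaussian1d", 64, 0.2, seed = 5)))
  counts <- rep(0, 64)
  for (s in 1:200)
    counts <- counts + (rowSums(maskEntries(makeMask("gaussian1d", 64, 0.2,
                                                     seed = s))) > 0)
  central <- 25:40  # central quartile of rows
  expect_true(which.max(counts) %in% central)
  expect_gt(mean(counts[central]), 2 * mean(counts[-central]))
})

test_that("applying a mask is an elementwise contraction", {
  x <- matrix(runif(16 * 16), 16)
  k <- forwardTransform(x)
  ones <- new("SamplingMask", pattern = "gaussian2d",
              entries = matrix(1, 16, 16), samplingRate = 1, seed = 0L)
  zeros <- new("SamplingMask", pattern = "gaussian2d",
               entries = matrix(0, 16, 16), samplingRate = 1e-6, seed = 0L)
  expect_identical(kspaceData(applyMask(k, ones)), kspaceData(k))
  expect_true(all(kspaceData(applyMask(k, zeros)) == 0))
  m <- makeMask("gaussian2d", 16, 0.5, seed = 3)
  expect_lte(sum(Mod(kspaceData(applyMask(k, m)))^2),
             sum(Mod(kspaceData(k))^2))
  bad <- makeMask("gaussian2d", 32, 0.5, seed = 3)
  expect_error(applyMask(k, bad), "shapes differ")
})

test_that("an all-ones mask makes zero-filling the identity", {
  im <- smallPhantom(5L, 16L)
  ones <- new("SamplingMask", pattern = "gaussian2d",
              entries = matrix(1, 16, 16), samplingRate = 1, seed = 0L)
  expect_lt(max(abs(imageData(zeroFilledRecon(im, ones)) - imageData(im))),
            1e-6)
})

test_that("zero-filled quality improves with sampling rate", {
  diffs <- sapply(1:10, function(s) {
    im <- makePhantom(phantomSpec(height = 64L, width = 64L, seed = 100L + s))
    p10 <- psnr(im, zeroFilledRecon(im, makeMask("gaussian1d", 64, 0.1, seed = s)))
    p30 <- psnr(im, zeroFilledRecon(im, makeMask("gaussian1d", 64, 0.3, seed = s)))
    p30 - p10
  })
  expect_gt(mean(diffs), 0)
})

test_that("acceleration factor is total over retained", {
  expect_equal(accelerationFactor(makeMask("gaussian1d", 100, 0.1, seed = 1)), 10)
  expect_equal(round(accelerationFactor(makeMask("gaussian1d", 100, 0.3, seed = 1)), 1), 3.3)
  expect_equal(accelerationFactor(makeMask("gaussian1d", 100, 0.2, seed = 1)), 5)
  ones <- new("SamplingMask", pattern = "gaussian1d",
              entries = matrix(1, 16, 16), samplingRate = 1, seed = 0L)
  expect_equal(accelerationFactor(ones), 1)
})
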
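test_that("PSNR closed forms and loop equivalence", {
  x <- matrix(runif(16 * 16, 0, 255), 16)
  expect_equal(psnr(x, x + 1), 20 * log10(255), tolerance = 1e-12)
  expect_equal(psnr(matrix(0, 16, 16), matrix(255, 16, 16)), 0)
  expect_equal(psnr(x, x), 100)  # declared cap
  expect_equal(psnr(x, x, cap = 60), 60)
  y <- x + matrix(rnorm(256, sd = 3), 16)
  acc <- 0
  for (i in 1:16) for (j in 1:16) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(psnr(x, y), 10 * log10(255^2 / (acc / 256)), tolerance = 1e-9)
  expect_equal(psnr(x + 7, y + 7), psnr(x, y), tolerance = 1e-9)  # shift sanity
  expect_error(psnr(x, matrix(0, 8, 8)), "mismatch")
})

test_that("global SSIM closed forms and direct evaluation", {
  x <- matrix(runif(16 * 16, 0, 255), 16)
  expect_identical(ssimGlobal(x, x), 1)
  C1 <- (0.01 * 255)^2
  a <- matrix(100, 16, 16); b <- matrix(200, 16, 16)
  expect_equal(ssimGlobal(a, b), (2 * 100 * 200 + C1) / (100^2 + 200^2 + C1),
               tolerance = 1e-12)
  y <- x + matrix(rnorm(256, sd = 10), 16)
  C2 <- (0.03 * 255)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ref <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssimGlobal(x, y), ref, tolerance = 1e-9)
})

test_that("windowed SSIM variant behaves and agrees on constant shifts", {
  x <- matrix(runif(32 * 32, 0, 255), 32)
  expect_equal(ssimGlobal(x, x, windowed = TRUE), 1, tolerance = 1e-12)
  w <- ssimGlobal(x, x + 20, windowed = TRUE)
  expect_true(w > 0 && w < 1)
})

test_that("NMSE closed forms and loop equivalence", {
  x <- matrix(runif(16 * 16, 1, 2), 16)
  expect_equal(nmse(x, x), 0)
  expect_equal(nmse(x, 2 * x), 1, tolerance = 1e-12)
  y <- x + matrix(rnorm(256, sd = 0.2), 16)
  num <- 0; den <- 0
  for (i in 1:16) for (j in 1:16) {
    num <- num + (x[i, j] - y[i, j])^2
    den <- den + x[i, j]^2
  }
  expect_equal(nmse(x, y), num / den, tolerance = 1e-9)
  expect_error(nmse(matrix(0, 16, 16), x), "all-zero")
})

test_that("the evaluation harness scores oracle and identity models correctly", {
  images <- lapply(1:4, function(s) smallPhantom(400L + s, 32L))
  conds <- data.frame(pattern = "gaussian1d", rate = c(0.1, 0.3))
  rep <- evaluateModel("oracle", images, conds, seed = 2L)
  expect_true(all(rep$perImage$psnr == 100))
  expect_true(all(rep$perImage$ssim == 1))
  expect_true(all(rep$perImage$nmse == 0))
  idrep <- evaluateModel("identity", images, conds, seed = 2L)
  # identity model reproduces the zero-filled baseline scores
  m <- makeMask("gaussian1d", 32, 0.1, seed = 3L)  # seed + ci with ci = 1
  zf <- zeroFilledRecon(images[[1]], m)
  expect_equal(idrep$perImage$psnr[1], psnr(images[[1]], zf), tolerance = 1e-12)
  # aggregate equals scalar re-aggregation of the per-image table
  g <- idrep$perImage[idrep$perImage$rate == 0.1, ]
  row <- idrep$summary[idrep$summary$rate == 0.1, ]
  expect_equal(row$psnrMean, mean(g$psnr), tolerance = 1e-12)
  expect_equal(row$psnrSd, sd(g$psnr), tolerance = 1e-12)
  expect_equal(row$nmseMean, mean(g$nmse), tolerance = 1e-12)
  # zero-filled PSNR non-decreasing in sampling rate
  expect_gte(idrep$summary$psnrMean[idrep$summary$rate == 0.3],
             idrep$summary$psnrMean[idrep$summary$rate == 0.1])
})

test_that("the harness writes CSV tables and handles noise conditions", {
  images <- lapply(1:2, function(s) smallPhantom(500L + s, 32L))
  conds <- data.frame(pattern = "gaussian1d", rate = 0.2)
  per <- file.path(tempdir(), "per.csv"); agg <- file.path(tempdir(), "agg.csv")
  rep <- evaluateModel("identity", images, conds, noiseLevels = c(Inf, 30),
                       seed = 4L, perImageCsv = per, summaryCsv = agg)
  expect_equal(nrow(rep$perImage), 4L)  # 2 images x 2 noise levels
  expect_equal(nrow(rep$summary), 2L)
  expect_true(file.exists(per) && file.exists(agg))
  # noise-free condition scores at least as well on average
  noisy <- rep$summary$psnrMean[is.finite(rep$summary$snrDb)]
  clean <- rep$summary$psnrMean[!is.finite(rep$summary$snrDb)]
  expect_gte(clean, noisy)
})
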
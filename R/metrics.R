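## Reconstruction quality metrics: PSNR, SSIM (global single-window form,
## with an optional sliding-window variant), NMSE, and the evaluation
## harness that scores a model over (mask pattern, rate, noise) conditions.

asMatrix255 <- function(x) {
  if (is(x, "MRImage")) {
    r <- x@intensityRange
    (x@data - r[1]) / (r[2] - r[1]) * 255
  } else x
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} in decibels with peak 255; inputs are
#' expected on the \code{[0, 255]} scale (MRImage inputs are rescaled from
#' their declared range automatically). Identical images map to the
#' declared \code{cap} value.
#'
#' @param x reference image (matrix on [0,255] or MRImage).
#' @param y test image.
#' @param peak peak signal value.
#' @param cap PSNR (dB) reported when MSE is exactly zero.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, peak = 255, cap = 100) {
  x <- asMatrix255(x); y <- asMatrix255(y)
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  mse <- mean((x - y)^2)
  if (mse == 0) return(cap)
  10 * log10(peak^2 / mse)
}

boxSums <- function(m, k) {
  # sums over all k x k windows (valid positions) via an integral image
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1, W + 1)
  P[-1, -1] <- cs
  i <- seq_len(H - k + 1); j <- seq_len(W - k + 1)
  P[i + k, j + k, drop = FALSE] - P[i, j + k, drop = FALSE] -
    P[i + k, j, drop = FALSE] + P[i, j, drop = FALSE]
}

#' Structural similarity index
#'
#' Single-window (whole-image) SSIM: luminance, contrast and structure
#' compared through global means, variances and covariance with the
#' standard stabilizers \code{C1 = (0.01 * 255)^2}, \code{C2 = (0.03 *
#' 255)^2}. Population (1/n) moments are used. Set \code{windowed = TRUE}
#' for a mean-of-local-windows variant (k x k sliding box windows).
#'
#' @param x,y images on the [0,255] scale (or MRImage, rescaled).
#' @param C1,C2 stabilizing constants.
#' @param windowed use the sliding-window variant instead of the global
#'   single-window form.
#' @param windowSize window side for the windowed variant.
#' @return SSIM value (1 for identical images).
#' @export
ssimGlobal <- function(x, y, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2,
                       windowed = FALSE, windowSize = 8L) {
  x <- asMatrix255(x); y <- asMatrix255(y)
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (!windowed) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  k <- as.integer(windowSize)
  n <- k * k
  sx <- boxSums(x, k) / n; sy <- boxSums(y, k) / n
  sxx <- boxSums(x * x, k) / n - sx^2
  syy <- boxSums(y * y, k) / n - sy^2
  sxy <- boxSums(x * y, k) / n - sx * sy
  mean(((2 * sx * sy + C1) * (2 * sxy + C2)) /
         ((sx^2 + sy^2 + C1) * (sxx + syy + C2)))
}

#' Normalized mean squared error
#'
#' Squared reconstruction error normalized by the reference's squared
#' norm: \code{sum((x - y)^2) / sum(x^2)}. Scale-free, used for
#' validation-time model selection.
#'
#' @param x reference image (matrix or MRImage; raw values are used).
#' @param y test image.
#' @return nonnegative NMSE.
#' @export
nmse <- function(x, y) {
  if (is(x, "MRImage")) x <- x@data
  if (is(y, "MRImage")) y <- y@data
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  sx <- sum(x^2)
  if (sx == 0) stop("NMSE undefined for an all-zero reference")
  sum((x - y)^2) / sx
}

#' Evaluate a reconstruction model over acquisition conditions
#'
#' For every (mask pattern, sampling rate, noise level) condition:
#' optionally corrupt each test image with AWGN, undersample it with a
#' condition-specific Gaussian mask, reconstruct, and score PSNR, SSIM and
#' NMSE against the clean fully sampled reference. Aggregates mean and
#' standard deviation per condition, in the usual test-set summary-table
#' layout.
#'
#' @param model a \linkS4class{ReconGenerator}, the string "identity"
#'   (score the zero-filled baseline), or the string "oracle" (a perfect
#'   model returning the reference; useful for harness checks).
#' @param images list of \linkS4class{MRImage} test images.
#' @param conditions data.frame with columns \code{pattern} and
#'   \code{rate} (one row per mask condition).
#' @param noiseLevels numeric vector of test SNRs in dB (use \code{Inf}
#'   for the noise-free condition).
#' @param seed base seed for masks and noise.
#' @param windowedSsim use windowed SSIM instead of the global form.
#' @param perImageCsv,summaryCsv optional paths to write CSV tables.
#' @return list of class "metricReport": \code{perImage} and
#'   \code{summary} data.frames.
#' @export
evaluateModel <- function(model, images, conditions,
                          noiseLevels = Inf, seed = 1L,
                          windowedSsim = FALSE,
                          perImageCsv = NULL, summaryCsv = NULL) {
  stopifnot(length(images) >= 1, nrow(conditions) >= 1)
  shape <- dim(images[[1]]@data)
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    pat <- as.character(conditions$pattern[ci])
    rate <- conditions$rate[ci]
    mask <- makeMask(pat, shape, rate, seed = seed + ci)
    for (snr in noiseLevels) {
      for (ii in seq_along(images)) {
        ref <- images[[ii]]
        src <- if (is.finite(snr)) addAwgn(ref, snr, seed = seed + 7000L + ii) else ref
        zf <- zeroFilledRecon(src, mask)
        rec <- if (identical(model, "identity")) zf
          else if (identical(model, "oracle")) ref
          else reconstructImage(model, zf)
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = pat, rate = rate, snrDb = snr, image = ii,
          psnr = psnr(ref, rec), ssim = ssimGlobal(ref, rec, windowed = windowedSsim),
          nmse = nmse(ref, rec))
      }
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per, interaction(per$pattern, per$rate, per$snrDb, drop = TRUE)),
    function(g) data.frame(
      pattern = g$pattern[1], rate = g$rate[1], snrDb = g$snrDb[1],
      psnrMean = mean(g$psnr), psnrSd = stats::sd(g$psnr),
      ssimMean = mean(g$ssim), ssimSd = stats::sd(g$ssim),
      nmseMean = mean(g$nmse), nmseSd = stats::sd(g$nmse))))
  rownames(agg) <- NULL
  if (!is.null(perImageCsv)) utils::write.csv(per, perImageCsv, row.names = FALSE)
  if (!is.null(summaryCsv)) utils::write.csv(agg, summaryCsv, row.names = FALSE)
  structure(list(perImage = per, summary = agg), class = "metricReport")
}
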
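## Centered orthonormal Fourier encoding, Gaussian undersampling masks,
## masked acquisition and zero-filled reconstruction.

## fftshift/ifftshift on matrices (DC between index 1 and the centered index
## floor(n/2)+1). For even sizes the two coincide; both are kept for clarity
## with odd sizes.
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - floor(h / 2)) %% h) + 1
  ci <- ((seq_len(w) - 1 - floor(w / 2)) %% w) + 1
  m[ri, ci, drop = FALSE]
}

ifftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 + floor(h / 2)) %% h) + 1
  ci <- ((seq_len(w) - 1 + floor(w / 2)) %% w) + 1
  m[ri, ci, drop = FALSE]
}

## Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Centered orthonormal 2D Fourier transform
#'
#' Maps an image to its k-space representation: a unitary 2D discrete
#' Fourier transform with the DC component shifted to the grid center.
#' With this scaling the transform preserves energy (Parseval), so the
#' frequency-domain loss and the pixel loss agree for real images.
#'
#' @param image an \linkS4class{MRImage} or a numeric matrix.
#' @return a \linkS4class{KSpaceGrid}.
#' @export
setGeneric("forwardTransform", function(image) standardGeneric("forwardTransform"))

#' @rdname forwardTransform
#' @export
setMethod("forwardTransform", "MRImage", function(image) {
  forwardTransform(image@data)
})

#' @rdname forwardTransform
#' @export
setMethod("forwardTransform", "matrix", function(image) {
  stopifnot(all(is.finite(image)))
  k <- fftshift2(stats::fft(image)) / sqrt(length(image))
  KSpaceGrid(k)
})

#' Inverse centered Fourier transform (magnitude image)
#'
#' Returns the magnitude of the unitary inverse DFT of a centered k-space
#' grid. Magnitude (not the complex pair) is the image handed to the
#' network; for fully sampled nonnegative images the round trip is exact to
#' numerical precision.
#'
#' @param kspace a \linkS4class{KSpaceGrid}.
#' @param intensityRange declared range of the resulting image.
#' @return an \linkS4class{MRImage}.
#' @export
setGeneric("inverseTransform", function(kspace, intensityRange = c(0, 1))
  standardGeneric("inverseTransform"))

#' @rdname inverseTransform
#' @export
setMethod("inverseTransform", "KSpaceGrid", function(kspace, intensityRange = c(0, 1)) {
  k <- kspace@data
  x <- stats::fft(ifftshift2(k), inverse = TRUE) / sqrt(length(k))
  MRImage(Mod(x), intensityRange)
})

#' Gaussian variable-density undersampling mask
#'
#' Draws a binary k-space sampling pattern with selection probability
#' proportional to a Gaussian density centered on the k-space center
#' (standard deviation 0.15 x grid extent). A low-frequency block is always
#' retained — 4% of phase-encode lines for \code{gaussian1d}, an 8 x 8
#' square for \code{gaussian2d} — and counts against the sampling budget.
#' The retained count is exact (\code{round(rate * lines)} full-width lines,
#' or \code{round(rate * cells)} points), guaranteeing the nominal
#' acceleration factor.
#'
#' @param pattern "gaussian1d" (whole phase-encode lines) or "gaussian2d"
#'   (individual points).
#' @param shape integer(2) grid size \code{c(H, W)} (a single integer is
#'   recycled to a square grid).
#' @param samplingRate retained fraction, strictly between 0 and 1.
#' @param seed integer seed; masks are a pure function of
#'   (pattern, shape, rate, seed).
#' @param densitySd Gaussian density standard deviation as a fraction of
#'   the grid extent.
#' @param centerFraction always-retained central line fraction (1D pattern).
#' @param centerBlock side of the always-retained central square (2D).
#' @return a \linkS4class{SamplingMask}.
#' @export
makeMask <- function(pattern = c("gaussian1d", "gaussian2d"), shape,
                     samplingRate, seed = 1L, densitySd = 0.15,
                     centerFraction = 0.04, centerBlock = 8L) {
  pattern <- match.arg(pattern)
  if (length(shape) == 1L) shape <- c(shape, shape)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  stopifnot(h >= 16L, w >= 16L)
  if (!(samplingRate > 0 && samplingRate < 1))
    stop("samplingRate must lie strictly between 0 and 1")
  entries <- matrix(0, h, w)
  ci <- floor(h / 2) + 1L
  cj <- floor(w / 2) + 1L
  if (pattern == "gaussian1d") {
    budget <- round(samplingRate * h)
    nc <- max(1L, round(centerFraction * h))
    if (nc > budget)
      stop("infeasible samplingRate: center block (", nc,
           " lines) exceeds the sampling budget (", budget, " lines)")
    centerRows <- ci - floor((nc - 1) / 2) + seq_len(nc) - 1L
    rows <- seq_len(h)
    wgt <- exp(-0.5 * ((rows - ci) / (densitySd * h))^2)
    free <- setdiff(rows, centerRows)
    extra <- with_seed(seed, {
      if (budget - nc > 0) sample(free, budget - nc, prob = wgt[free]) else integer(0)
    })
    entries[c(centerRows, extra), ] <- 1
  } else {
    budget <- round(samplingRate * h * w)
    cb <- as.integer(centerBlock)
    crows <- ci - floor((cb - 1) / 2) + seq_len(cb) - 1L
    ccols <- cj - floor((cb - 1) / 2) + seq_len(cb) - 1L
    if (cb * cb > budget)
      stop("infeasible samplingRate: ", cb, "x", cb,
           " center block exceeds the sampling budget (", budget, " points)")
    center <- as.vector(outer(crows, (ccols - 1L) * h, `+`))
    rw <- exp(-0.5 * ((seq_len(h) - ci) / (densitySd * h))^2)
    cw <- exp(-0.5 * ((seq_len(w) - cj) / (densitySd * w))^2)
    wgt <- as.vector(outer(rw, cw))
    free <- setdiff(seq_len(h * w), center)
    extra <- with_seed(seed, {
      if (budget - cb * cb > 0)
        sample(free, budget - cb * cb, prob = wgt[free]) else integer(0)
    })
    entries[c(center, extra)] <- 1
  }
  new("SamplingMask", pattern = pattern, entries = entries,
      samplingRate = samplingRate, seed = as.integer(seed))
}

#' Apply a sampling mask to k-space data
#'
#' Elementwise product of a k-space grid with a binary mask; unsampled
#' entries become zero (masked acquisition).
#'
#' @param kspace a \linkS4class{KSpaceGrid}.
#' @param mask a \linkS4class{SamplingMask}.
#' @return a \linkS4class{KSpaceGrid}.
#' @export
setGeneric("applyMask", function(kspace, mask) standardGeneric("applyMask"))

#' @rdname applyMask
#' @export
setMethod("applyMask", signature("KSpaceGrid", "SamplingMask"), function(kspace, mask) {
  if (!identical(dim(kspace@data), dim(mask@entries)))
    stop("k-space and mask shapes differ")
  KSpaceGrid(kspace@data * mask@entries)
})

#' Zero-filled reconstruction
#'
#' Fourier-transforms an image, discards the unsampled k-space entries and
#' inverts: the aliased image a network-based de-aliaser takes as input.
#'
#' @param image an \linkS4class{MRImage}.
#' @param mask a \linkS4class{SamplingMask} of matching shape.
#' @return an \linkS4class{MRImage} on the same declared range as the input.
#' @export
setGeneric("zeroFilledRecon", function(image, mask) standardGeneric("zeroFilledRecon"))

#' @rdname zeroFilledRecon
#' @export
setMethod("zeroFilledRecon", signature("MRImage", "SamplingMask"), function(image, mask) {
  inverseTransform(applyMask(forwardTransform(image), mask),
                   intensityRange = image@intensityRange)
})

#' Acceleration factor of a sampling mask
#'
#' Reciprocal of the realized retained fraction: total phase-encode lines
#' over retained lines for 1D masks, total entries over retained entries
#' for 2D masks. A mask keeping 10% of lines accelerates acquisition 10x.
#'
#' @param mask a \linkS4class{SamplingMask}.
#' @return a positive number.
#' @export
setGeneric("accelerationFactor", function(mask) standardGeneric("accelerationFactor"))

#' @rdname accelerationFactor
#' @export
setMethod("accelerationFactor", "SamplingMask", function(mask) {
  e <- mask@entries
  if (mask@pattern == "gaussian1d") {
    kept <- sum(rowSums(e) > 0)
    if (kept == 0) stop("mask retains no lines")
    nrow(e) / kept
  } else {
    kept <- sum(e == 1)
    if (kept == 0) stop("mask retains no entries")
    length(e) / kept
  }
})
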
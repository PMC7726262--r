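## Synthetic brain-like phantoms: overlapping uniform ellipses composited
## back-to-front plus low-pass-filtered Gaussian texture, augmentation in
## the style used for MR training sets, and AWGN at an exact target SNR.

#' Phantom specification
#'
#' @param height,width image size in pixels (>= 16).
#' @param nEllipses number of uniform-intensity ellipses (>= 1); the first
#'   is a large head-like ellipse, later ones are composited on top.
#' @param textureAmplitude amplitude of the smooth texture field as a
#'   fraction of the dynamic range, in [0, 1].
#' @param intensityRange numeric(2) output range.
#' @param seed integer; phantoms are a pure function of the spec.
#' @return a list of class "phantomSpec".
#' @export
phantomSpec <- function(height = 64L, width = 64L, nEllipses = 8L,
                        textureAmplitude = 0.15, intensityRange = c(0, 1),
                        seed = 1L) {
  if (height < 16 || width < 16) stop("invalid spec: dimensions must be >= 16")
  if (nEllipses < 1) stop("invalid spec: nEllipses must be >= 1")
  if (textureAmplitude < 0 || textureAmplitude > 1)
    stop("invalid spec: textureAmplitude must lie in [0, 1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nEllipses = as.integer(nEllipses),
                 textureAmplitude = textureAmplitude,
                 intensityRange = as.numeric(intensityRange),
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

## Circular Gaussian blur via FFT; sigma in pixels.
gaussianBlur <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  dr <- pmin(seq_len(h) - 1, h - (seq_len(h) - 1))
  dc <- pmin(seq_len(w) - 1, w - (seq_len(w) - 1))
  kr <- exp(-0.5 * (dr / sigma)^2)
  kc <- exp(-0.5 * (dc / sigma)^2)
  ker <- outer(kr, kc)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(m) * stats::fft(ker), inverse = TRUE)) / (h * w)
}

#' Generate a brain-like phantom image
#'
#' Composites \code{nEllipses} uniform-intensity ellipses back-to-front
#' (the first spans most of the field of view like a head outline; later
#' ellipses are smaller interior structures), then adds a low-pass-filtered
#' Gaussian noise texture inside the head region. The result is
#' piecewise-smooth with sharp edges — the regime where undersampling
#' aliasing is visible — plus fine texture that exercises detail recovery.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return an \linkS4class{MRImage} on \code{spec$intensityRange}.
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  h <- spec$height; w <- spec$width
  lo <- spec$intensityRange[1]; hi <- spec$intensityRange[2]
  dr <- hi - lo
  with_seed(spec$seed, {
    img <- matrix(lo, h, w)
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(rep(seq_len(h), times = w), h, w)
    head_mask <- NULL
    for (e in seq_len(spec$nEllipses)) {
      if (e == 1L) {
        cx <- (w + 1) / 2; cy <- (h + 1) / 2
        a <- 0.42 * w; b <- 0.46 * h; th <- 0
        val <- lo + dr * stats::runif(1, 0.25, 0.45)
      } else {
        cx <- stats::runif(1, 0.3 * w, 0.7 * w)
        cy <- stats::runif(1, 0.3 * h, 0.7 * h)
        a <- stats::runif(1, 0.05, 0.22) * w
        b <- stats::runif(1, 0.05, 0.22) * h
        th <- stats::runif(1, 0, pi)
        val <- lo + dr * stats::runif(1, 0.3, 1)
      }
      xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      img[inside] <- val
      if (e == 1L) head_mask <- inside
    }
    if (spec$textureAmplitude > 0) {
      tex <- gaussianBlur(matrix(stats::rnorm(h * w), h, w), max(1, min(h, w) / 24))
      tex <- tex / max(abs(tex))
      img[head_mask] <- img[head_mask] +
        spec$textureAmplitude * dr * tex[head_mask]
      img <- pmin(pmax(img, lo), hi)
    }
    MRImage(img, spec$intensityRange)
  })
}

#' Augmentation specification
#'
#' Symmetric random-augmentation ranges for training images: left-right
#' flip, rotation up to +/-20 degrees, shifts up to 10% of the image size,
#' zoom in [0.9, 1.1], additive brightness jitter, and a Simard-style
#' random elastic deformation with displacement amplitude
#' \code{elasticAlpha = 255 * 3} pixels applied to a unit noise field
#' smoothed with \code{elasticSigma = 255 * 0.10} pixels.
#'
#' @param flipLr enable random left-right flip (probability 1/2).
#' @param rotateDegMax maximum rotation magnitude in degrees.
#' @param shiftFrac maximum shift as a fraction of each axis.
#' @param zoomRange numeric(2) zoom factor range.
#' @param brightnessJitter maximum additive brightness change as a fraction
#'   of the dynamic range.
#' @param elasticAlpha elastic displacement scale in pixels (0 disables).
#' @param elasticSigma elastic smoothing standard deviation in pixels.
#' @param seed integer seed.
#' @return a list of class "augmentSpec".
#' @export
augmentSpec <- function(flipLr = TRUE, rotateDegMax = 20, shiftFrac = 0.10,
                        zoomRange = c(0.9, 1.1), brightnessJitter = 0.05,
                        elasticAlpha = 255 * 3, elasticSigma = 255 * 0.10,
                        seed = 1L) {
  if (elasticAlpha > 0 && elasticSigma <= 0)
    stop("elasticSigma must be > 0 when elastic deformation is enabled")
  structure(list(flipLr = isTRUE(flipLr), rotateDegMax = rotateDegMax,
                 shiftFrac = shiftFrac, zoomRange = as.numeric(zoomRange),
                 brightnessJitter = brightnessJitter,
                 elasticAlpha = elasticAlpha, elasticSigma = elasticSigma,
                 seed = as.integer(seed)),
            class = "augmentSpec")
}

## Mirror-reflect an index vector into [1, n].
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1) %% p
  i <- ifelse(i < 0, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

#' Warp an image by an affine + elastic displacement
#'
#' Deterministic resampling backbone of \code{\link{augmentImage}}: inverse
#' bilinear warp about the image center with reflect border handling. With
#' all arguments at their defaults the mapping is the identity and the
#' output equals the input pixel-exactly.
#'
#' @param img numeric matrix.
#' @param angleDeg rotation angle in degrees (counterclockwise).
#' @param shift numeric(2) (row, col) translation in pixels.
#' @param zoom scalar zoom factor (> 1 magnifies).
#' @param flip logical; left-right flip.
#' @param dxy optional list(dr, dc) of per-pixel displacement matrices.
#' @return warped numeric matrix of the same shape.
#' @export
warpImage <- function(img, angleDeg = 0, shift = c(0, 0), zoom = 1,
                      flip = FALSE, dxy = NULL) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- matrix(rep(seq_len(h), times = w), h, w)   # row index
  C <- matrix(rep(seq_len(w), each = h), h, w)    # col index
  if (flip) C <- w + 1 - C
  th <- angleDeg * pi / 180
  # inverse map: source = center + R(-th)/zoom * (target - center - shift)
  tr <- R - cy - shift[1]
  tc <- C - cx - shift[2]
  sr <- cy + (cos(th) * tr - sin(th) * tc) / zoom
  sc <- cx + (sin(th) * tr + cos(th) * tc) / zoom
  if (!is.null(dxy)) {
    sr <- sr + dxy$dr
    sc <- sc + dxy$dc
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(reflectIndex(r0, h), reflectIndex(c0, w))
  i01 <- cbind(reflectIndex(r0, h), reflectIndex(c0 + 1, w))
  i10 <- cbind(reflectIndex(r0 + 1, h), reflectIndex(c0, w))
  i11 <- cbind(reflectIndex(r0 + 1, h), reflectIndex(c0 + 1, w))
  out <- (1 - fr) * (1 - fc) * img[i00] + (1 - fr) * fc * img[i01] +
    fr * (1 - fc) * img[i10] + fr * fc * img[i11]
  matrix(out, h, w)
}

#' Randomly augment an image
#'
#' Draws one transform from the declared symmetric ranges (flip, rotation,
#' shift, zoom, brightness, elastic deformation) and applies it with
#' bilinear resampling and reflect borders. Out-of-range intensities are
#' clipped back to the image's declared range. Deterministic per seed; an
#' identity-configured spec returns the input pixel-exactly.
#'
#' @param image an \linkS4class{MRImage}.
#' @param spec an \code{\link{augmentSpec}}.
#' @return an augmented \linkS4class{MRImage}.
#' @export
augmentImage <- function(image, spec) {
  stopifnot(is(image, "MRImage"), inherits(spec, "augmentSpec"))
  img <- image@data
  rng <- image@intensityRange
  with_seed(spec$seed, {
    flip <- spec$flipLr && stats::runif(1) < 0.5
    ang <- if (spec$rotateDegMax > 0)
      stats::runif(1, -spec$rotateDegMax, spec$rotateDegMax) else 0
    shift <- if (spec$shiftFrac > 0)
      c(stats::runif(1, -1, 1) * spec$shiftFrac * nrow(img),
        stats::runif(1, -1, 1) * spec$shiftFrac * ncol(img)) else c(0, 0)
    zoom <- if (diff(spec$zoomRange) > 0)
      stats::runif(1, spec$zoomRange[1], spec$zoomRange[2]) else spec$zoomRange[1]
    bright <- if (spec$brightnessJitter > 0)
      stats::runif(1, -1, 1) * spec$brightnessJitter * diff(rng) else 0
    dxy <- NULL
    if (spec$elasticAlpha > 0) {
      h <- nrow(img); w <- ncol(img)
      dr <- gaussianBlur(matrix(stats::runif(h * w, -1, 1), h, w), spec$elasticSigma)
      dc <- gaussianBlur(matrix(stats::runif(h * w, -1, 1), h, w), spec$elasticSigma)
      dxy <- list(dr = spec$elasticAlpha * dr, dc = spec$elasticAlpha * dc)
    }
    out <- warpImage(img, angleDeg = ang, shift = shift, zoom = zoom,
                     flip = flip, dxy = dxy)
    if (bright != 0) out <- out + bright
    if (!identical(out, img)) out <- pmin(pmax(out, rng[1]), rng[2])
    MRImage(out, rng)
  })
}

#' Add white Gaussian noise at an exact target SNR
#'
#' Adds a zero-mean Gaussian noise field in the image domain, scaled so the
#' realized sample satisfies
#' \code{10 * log10(mean(x^2) / mean(n^2)) == snrDb} exactly. Pass
#' \code{snrDb = Inf} to disable noise.
#'
#' @param image an \linkS4class{MRImage} with nonzero signal power.
#' @param snrDb target signal-to-noise ratio in decibels.
#' @param seed integer seed; the noise field is a pure function of it.
#' @return a noisy \linkS4class{MRImage} (not clipped, so the realized SNR
#'   is preserved).
#' @export
addAwgn <- function(image, snrDb, seed = 1L) {
  stopifnot(is(image, "MRImage"))
  if (is.infinite(snrDb) && snrDb > 0) return(image)
  x <- image@data
  p <- mean(x^2)
  if (p == 0) stop("undefined SNR: image has zero signal power")
  noise <- with_seed(seed, matrix(stats::rnorm(length(x)), nrow(x)))
  target <- p / 10^(snrDb / 10)
  noise <- noise * sqrt(target / mean(noise^2))
  MRImage(x + noise, image@intensityRange)
}

#' Generate disjoint seeded train/validation/test splits
#'
#' Each image gets its own derived seed (offset by split), so splits are
#' disjoint and the whole dataset regenerates bit-exactly from the master
#' seed in the phantom spec. Augmentation is applied to the training split
#' only.
#'
#' @param nTrain,nVal,nTest split sizes (>= 1).
#' @param spec a \code{\link{phantomSpec}}; its \code{seed} is the master
#'   seed.
#' @param augment an \code{\link{augmentSpec}} applied to training images,
#'   or NULL to disable augmentation.
#' @return a list of class "csganDataset" with elements \code{train},
#'   \code{val}, \code{test} (lists of \linkS4class{MRImage}) and
#'   \code{manifest} (data.frame of split, index, seed).
#' @export
makeDataset <- function(nTrain, nVal, nTest, spec, augment = NULL) {
  stopifnot(inherits(spec, "phantomSpec"), nTrain >= 1, nVal >= 1, nTest >= 1)
  base <- spec$seed
  gen <- function(n, offset, doAug) {
    lapply(seq_len(n), function(i) {
      s <- spec; s$seed <- as.integer(base + offset + i)
      im <- makePhantom(s)
      if (doAug && !is.null(augment)) {
        a <- augment; a$seed <- as.integer(base + offset + i + 500000L)
        im <- augmentImage(im, a)
      }
      im
    })
  }
  train <- gen(nTrain, 0L, TRUE)
  val <- gen(nVal, 1000000L, FALSE)
  test <- gen(nTest, 2000000L, FALSE)
  manifest <- data.frame(
    split = rep(c("train", "val", "test"), c(nTrain, nVal, nTest)),
    index = c(seq_len(nTrain), seq_len(nVal), seq_len(nTest)),
    seed = c(base + seq_len(nTrain), base + 1000000L + seq_len(nVal),
             base + 2000000L + seq_len(nTest)))
  structure(list(train = train, val = val, test = test, manifest = manifest),
            class = "csganDataset")
}
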
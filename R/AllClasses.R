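#' @import methods
NULL

#' MRImage: a real-valued 2D magnitude image
#'
#' Container for a single-channel magnitude MR (or MR-like) image together
#' with its declared intensity range. Images live on one of two scales in
#' this package: acquisition scale (the phantom generator's
#' \code{intensityRange}, by default \code{[0, 1]}) and network scale
#' \code{[-1, 1]}; metrics are always computed after rescaling to
#' \code{[0, 255]}.
#'
#' @slot data numeric matrix (height x width), finite.
#' @slot intensityRange numeric(2), declared \code{c(lo, hi)} with lo < hi.
#' @export
setClass("MRImage", representation(
  data = "matrix",
  intensityRange = "numeric"
))

setValidity("MRImage", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 16L || ncol(d) < 16L) return("image must be at least 16 x 16")
  if (!all(is.finite(d))) return("image values must be finite")
  r <- object@intensityRange
  if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
    return("intensityRange must be c(lo, hi) with lo < hi")
  TRUE
})

#' Construct an MRImage
#'
#' @param data numeric matrix of pixel values.
#' @param intensityRange declared intensity range \code{c(lo, hi)}.
#' @return an \linkS4class{MRImage}.
#' @export
MRImage <- function(data, intensityRange = c(0, 1)) {
  new("MRImage", data = data, intensityRange = as.numeric(intensityRange))
}

#' KSpaceGrid: centered complex spatial-frequency data
#'
#' Complex H x W grid produced by the centered orthonormal 2D Fourier
#' transform of an image; the DC component sits at index
#' \code{(floor(H/2)+1, floor(W/2)+1)}.
#'
#' @slot data complex matrix.
#' @export
setClass("KSpaceGrid", representation(data = "matrix"))

setValidity("KSpaceGrid", function(object) {
  if (!is.complex(object@data)) return("k-space data must be complex")
  if (any(!is.finite(Re(object@data))) || any(!is.finite(Im(object@data))))
    return("k-space values must be finite")
  TRUE
})

#' Construct a KSpaceGrid
#' @param data complex matrix (DC at the centered index).
#' @return a \linkS4class{KSpaceGrid}.
#' @export
KSpaceGrid <- function(data) {
  storage.mode(data) <- "complex"
  new("KSpaceGrid", data = data)
}

#' SamplingMask: binary k-space undersampling pattern
#'
#' A Gaussian variable-density undersampling mask in centered k-space
#' coordinates. \code{gaussian1d} masks retain whole phase-encode lines
#' (rows); \code{gaussian2d} masks retain individual points. The retained
#' count is exact: \code{round(rate * H)} lines or
#' \code{round(rate * H * W)} points, so the nominal acceleration factor is
#' honored exactly.
#'
#' @slot pattern "gaussian1d" or "gaussian2d".
#' @slot entries binary (0/1) numeric matrix.
#' @slot samplingRate retained fraction in (0, 1].
#' @slot seed integer seed the mask was drawn with.
#' @export
setClass("SamplingMask", representation(
  pattern = "character",
  entries = "matrix",
  samplingRate = "numeric",
  seed = "integer"
))

setValidity("SamplingMask", function(object) {
  if (!object@pattern %in% c("gaussian1d", "gaussian2d"))
    return("pattern must be 'gaussian1d' or 'gaussian2d'")
  e <- object@entries
  if (!all(e %in% c(0, 1))) return("mask entries must be 0/1")
  if (object@pattern == "gaussian1d") {
    rowfull <- apply(e, 1L, function(r) all(r == r[1]))
    if (!all(rowfull))
      return("gaussian1d mask rows must be constant along the frequency-encode axis")
  }
  if (object@samplingRate <= 0 || object@samplingRate > 1)
    return("samplingRate must be in (0, 1]")
  TRUE
})

## ---- accessors ----

#' Extract the pixel matrix of an MRImage
#' @param x an MRImage.
#' @return numeric matrix.
#' @export
imageData <- function(x) {
  stopifnot(is(x, "MRImage"))
  x@data
}

#' Declared intensity range of an MRImage
#' @param x an MRImage.
#' @return numeric(2).
#' @export
intensityRange <- function(x) {
  stopifnot(is(x, "MRImage"))
  x@intensityRange
}

#' Extract the complex matrix of a KSpaceGrid
#' @param x a KSpaceGrid.
#' @return complex matrix.
#' @export
kspaceData <- function(x) {
  stopifnot(is(x, "KSpaceGrid"))
  x@data
}

#' Extract the binary matrix of a SamplingMask
#' @param x a SamplingMask.
#' @return numeric 0/1 matrix.
#' @export
maskEntries <- function(x) {
  stopifnot(is(x, "SamplingMask"))
  x@entries
}

#' Nominal sampling rate of a SamplingMask
#' @param x a SamplingMask.
#' @return fraction of k-space retained (nominal).
#' @export
samplingRate <- function(x) {
  stopifnot(is(x, "SamplingMask"))
  x@samplingRate
}

## ---- show methods ----

setMethod("show", "MRImage", function(object) {
  d <- object@data
  cat(sprintf(
    "MRImage %d x %d, declared range [%g, %g], values in [%.4g, %.4g]\n",
    nrow(d), ncol(d), object@intensityRange[1], object@intensityRange[2],
    min(d), max(d)))
})

setMethod("show", "KSpaceGrid", function(object) {
  d <- object@data
  cat(sprintf("KSpaceGrid %d x %d (centered), energy %.6g\n",
              nrow(d), ncol(d), sum(Mod(d)^2)))
})

setMethod("show", "SamplingMask", function(object) {
  e <- object@entries
  cat(sprintf(
    "SamplingMask %s %d x %d, nominal rate %.3f, retained %d/%d (%.1fx acceleration)\n",
    object@pattern, nrow(e), ncol(e), object@samplingRate,
    sum(e == 1), length(e), length(e) / max(1, sum(e == 1))))
})
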
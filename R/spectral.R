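## Spectral normalization: power-iteration estimate of a weight matrix's
## largest singular value, and division by it so every layer satisfies a
## 1-Lipschitz bound. Convolution kernels are already stored flattened as
## (output-channels x everything-else) matrices, which is the shape the
## estimate operates on.

#' Create a spectral-normalization state
#'
#' Holds the persistent left-singular-vector estimate \code{u} (unit norm,
#' seeded standard-normal initialization) and the per-call power-iteration
#' count.
#'
#' @param weight the weight matrix the state will track.
#' @param seed integer seed for the initialization of \code{u}.
#' @param nPowerIterations power iterations per \code{\link{estimateSigma}}
#'   call (one per training step is standard).
#' @return list of class "spectralState".
#' @export
spectralState <- function(weight, seed = 1L, nPowerIterations = 1L) {
  u <- with_seed(seed, stats::rnorm(nrow(weight)))
  u <- u / sqrt(sum(u^2))
  structure(list(u = u, nPowerIterations = as.integer(nPowerIterations)),
            class = "spectralState")
}

#' Estimate the largest singular value by power iteration
#'
#' Runs \code{state$nPowerIterations} (or \code{nIter}) rounds of
#' \code{v <- normalize(t(W) u); u <- normalize(W v)} and returns
#' \code{sigma = u' W v} together with the updated state, which persists
#' across training steps so a single iteration per step converges.
#'
#' @param weight nonzero numeric matrix (conv kernels flattened to
#'   output-channels x everything-else).
#' @param state a \code{\link{spectralState}}.
#' @param nIter override for the iteration count.
#' @return list(sigma, state, v).
#' @export
estimateSigma <- function(weight, state, nIter = NULL) {
  if (all(weight == 0)) stop("zero matrix has no spectral direction")
  n <- if (is.null(nIter)) state$nPowerIterations else as.integer(nIter)
  u <- state$u
  v <- NULL
  for (i in seq_len(max(1L, n))) {
    v <- drop(crossprod(weight, u))
    v <- v / sqrt(sum(v^2))
    u <- drop(weight %*% v)
    u <- u / sqrt(sum(u^2))
  }
  sigma <- drop(crossprod(u, weight %*% v))
  state$u <- u
  list(sigma = as.numeric(sigma), state = state, v = v)
}

#' Spectrally normalize a weight matrix
#'
#' Divides the weight by its estimated largest singular value so the
#' returned matrix has spectral norm 1 (within power-iteration accuracy).
#' Scale-invariant: \code{normalizeWeight(10 * W)} equals
#' \code{normalizeWeight(W)}.
#'
#' @inheritParams estimateSigma
#' @return list(weight, state, sigma, u, v); \code{u}, \code{v} are the
#'   singular-direction estimates used (needed for the training-time
#'   gradient of the normalization).
#' @export
normalizeWeight <- function(weight, state, nIter = NULL) {
  est <- estimateSigma(weight, state, nIter)
  list(weight = weight / est$sigma, state = est$state, sigma = est$sigma,
       u = est$state$u, v = est$v)
}
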
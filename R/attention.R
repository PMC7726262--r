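## Self-attention over spatial locations of a feature map: 1x1 projections
## f, g, h, a softmax attention map over all location pairs, an output
## projection v, and a learnable residual blend initialized so the module
## is the identity.

#' Initialize self-attention parameters
#'
#' 1x1 (location-wise) projection matrices: query/key projections to C/8
#' channels, value and output projections at C channels, and the residual
#' blend coefficient \code{gamma} initialized to 0 so a freshly built
#' module is the identity map.
#'
#' @param channels feature channel count C (divisible by 8).
#' @param seed integer seed for the Gaussian initialization.
#' @param sd initialization standard deviation.
#' @return list of class "attentionParams" with Wf, Wg (C/8 x C), Wh, Wv
#'   (C x C) and gamma.
#' @export
initAttentionParams <- function(channels, seed = 1L, sd = NULL) {
  if (channels %% 8 != 0) stop("attention channel count must be divisible by 8")
  c8 <- channels %/% 8
  if (is.null(sd)) sd <- sqrt(2 / channels)
  with_seed(seed, {
    structure(list(
      Wf = matrix(stats::rnorm(c8 * channels, sd = sd), c8, channels),
      Wg = matrix(stats::rnorm(c8 * channels, sd = sd), c8, channels),
      Wh = matrix(stats::rnorm(channels * channels, sd = sd), channels, channels),
      Wv = matrix(stats::rnorm(channels * channels, sd = sd), channels, channels),
      gamma = 0), class = "attentionParams")
  })
}

## feature array (H, W, C) <-> C x N matrix with x_i as column i
## (locations flattened column-major).
featToMat <- function(feat) {
  d <- dim(feat)
  t(matrix(feat, d[1] * d[2], d[3]))
}

matToFeat <- function(m, h, w) {
  array(t(m), dim = c(h, w, nrow(m)))
}

#' Pairwise attention scores
#'
#' \code{s[i, j] = <Wf x_i, Wg x_j>} over all pairs of the N = H*W
#' flattened spatial locations.
#'
#' @param feat numeric array (H, W, C) with C divisible by 8.
#' @param params an \code{\link{initAttentionParams}} list.
#' @return N x N score matrix.
#' @export
attentionScores <- function(feat, params) {
  X <- featToMat(feat)
  if (ncol(params$Wf) != nrow(X)) stop("channel mismatch between feature map and params")
  crossprod(params$Wf %*% X, params$Wg %*% X)  # t(F) %*% G
}

#' Softmax attention map
#'
#' Normalizes scores over source locations i for each query location j:
#' \code{beta[j, i] = exp(s[i, j]) / sum_i exp(s[i, j])}. The map is stored
#' query-major (row j sums to 1). A per-query maximum is subtracted before
#' exponentiation so large scores cannot overflow.
#'
#' @param scores N x N score matrix from \code{\link{attentionScores}}.
#' @return N x N row-stochastic matrix (class "attentionMap" attribute-free).
#' @export
attentionMap <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  mx <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, mx))
  t(sweep(e, 2, colSums(e), "/"))
}

#' Attention output projection
#'
#' \code{o_j = Wv (sum_i beta[j, i] Wh x_i)}, reshaped back to the input's
#' (H, W, C) layout.
#'
#' @param beta N x N attention map (query-major).
#' @param feat numeric array (H, W, C).
#' @param params attention parameters.
#' @return numeric array (H, W, C).
#' @export
attentionOutput <- function(beta, feat, params) {
  d <- dim(feat)
  X <- featToMat(feat)
  if (nrow(beta) != ncol(X) || ncol(beta) != ncol(X)) stop("shape mismatch")
  O <- params$Wv %*% ((params$Wh %*% X) %*% t(beta))
  matToFeat(O, d[1], d[2])
}

#' Self-attention module forward pass
#'
#' Composes scores, softmax map and output projection, then blends with
#' the input through the learnable coefficient:
#' \code{y = gamma * o + x}. With \code{gamma = 0} (the initialization)
#' the module is the pixel-exact identity.
#'
#' @param feat numeric array (H, W, C), C divisible by 8.
#' @param params attention parameters.
#' @return numeric array (H, W, C).
#' @export
selfAttentionForward <- function(feat, params) {
  if (params$gamma == 0) return(feat)
  beta <- attentionMap(attentionScores(feat, params))
  params$gamma * attentionOutput(beta, feat, params) + feat
}

## Forward with cache for training; always computes the attention path so
## gamma receives a gradient even at gamma = 0.
attnFwdCache <- function(feat, params) {
  d <- dim(feat)
  X <- featToMat(feat)
  Fm <- params$Wf %*% X
  Gm <- params$Wg %*% X
  S <- crossprod(Fm, Gm)
  A <- { # column-stochastic softmax over i (A[i, j] = beta[j, i])
    mx <- apply(S, 2, max)
    e <- exp(sweep(S, 2, mx))
    sweep(e, 2, colSums(e), "/")
  }
  Hm <- params$Wh %*% X
  O1 <- Hm %*% A
  O <- params$Wv %*% O1
  Y <- params$gamma * O + X
  list(y = matToFeat(Y, d[1], d[2]),
       cache = list(X = X, Fm = Fm, Gm = Gm, A = A, Hm = Hm, O1 = O1, O = O,
                    h = d[1], w = d[2]))
}

## Backward: gy is (H, W, C). Returns input gradient and parameter grads.
attnBwd <- function(gy, params, cache) {
  gY <- featToMat(gy)
  ggamma <- sum(gY * cache$O)
  gO <- params$gamma * gY
  gWv <- gO %*% t(cache$O1)
  gO1 <- crossprod(params$Wv, gO)
  gHm <- gO1 %*% t(cache$A)
  gA <- crossprod(cache$Hm, gO1)
  # softmax backward per column j
  gS <- cache$A * sweep(gA, 2, colSums(gA * cache$A))
  gF <- cache$Gm %*% t(gS)
  gG <- cache$Fm %*% gS
  gWf <- gF %*% t(cache$X)
  gWg <- gG %*% t(cache$X)
  gWh <- gHm %*% t(cache$X)
  gX <- gY + crossprod(params$Wf, gF) + crossprod(params$Wg, gG) +
    crossprod(params$Wh, gHm)
  list(gx = matToFeat(gX, cache$h, cache$w),
       grads = list(Wf = gWf, Wg = gWg, Wh = gWh, Wv = gWv, gamma = ggamma))
}

#' Render an attention map row as a heatmap PNG
#'
#' Reshapes row \code{j} of a query-major attention map back to the
#' feature map's H x W layout and writes an 8-bit grayscale PNG for
#' inspection.
#'
#' @param beta N x N attention map.
#' @param j query location index.
#' @param h,w spatial size with \code{h * w == N}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeAttentionHeatmap <- function(beta, j, h, w, path) {
  stopifnot(h * w == ncol(beta))
  m <- matrix(beta[j, ], h, w)
  m <- m / max(m)
  png::writePNG(m, path)
  invisible(path)
}
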
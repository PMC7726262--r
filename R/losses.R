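## Relativistic average adversarial losses and the content losses (pixel,
## frequency-domain, perceptual) combined into the total generator
## objective. All squared-error losses use the 1/2 * mean convention so
## the published weights balance terms independently of image size.

logSigmoid <- function(t) {
  # log(1/(1+exp(-t))) without overflow for |t| up to ~1e4 and beyond
  ifelse(t >= 0, -log1p(exp(-t)), t - log1p(exp(t)))
}

checkScores <- function(realScores, fakeScores) {
  if (length(realScores) == 0 || length(fakeScores) == 0)
    stop("empty score batch")
  if (any(!is.finite(realScores)) || any(!is.finite(fakeScores)))
    stop("scores must be finite")
}

#' Relativistic average discriminator loss
#'
#' The discriminator scores how much more realistic a real image is than
#' the batch-average fake (and vice versa):
#' \code{D(x) = sigmoid(C(x) - mean C(fake))},
#' \code{D(fake) = sigmoid(C(fake) - mean C(real))}, and the loss is
#' \code{-mean log D(x) - mean log(1 - D(fake))}, evaluated in
#' log-sigmoid form for numerical stability. When every real and fake
#' score coincide the loss is exactly \code{2 log 2}.
#'
#' @param realScores raw discriminator outputs C(x) on the real batch.
#' @param fakeScores raw outputs C(G(z)) on the fake batch.
#' @return nonnegative loss value.
#' @export
raDiscriminatorLoss <- function(realScores, fakeScores) {
  checkScores(realScores, fakeScores)
  a <- realScores - mean(fakeScores)
  b <- fakeScores - mean(realScores)
  # log(1 - sigmoid(b)) = logSigmoid(-b)
  -mean(logSigmoid(a)) - mean(logSigmoid(-b))
}

#' Relativistic average generator adversarial loss
#'
#' Mirror of \code{\link{raDiscriminatorLoss}} with the roles of real and
#' fake exchanged: \code{-mean log D(fake) - mean log(1 - D(x))} with the
#' same relativistic sigmoids. Swapping the two score lists exchanges the
#' generator and discriminator losses.
#'
#' @inheritParams raDiscriminatorLoss
#' @return nonnegative loss value.
#' @export
raGeneratorLoss <- function(realScores, fakeScores) {
  checkScores(realScores, fakeScores)
  a <- realScores - mean(fakeScores)
  b <- fakeScores - mean(realScores)
  -mean(logSigmoid(b)) - mean(logSigmoid(-a))
}

#' Pixel-domain content loss
#'
#' \code{1/2 * mean((x_t - x_u)^2)} between the fully sampled image and
#' the reconstruction.
#'
#' @param xt,xu matrices or \linkS4class{MRImage}s of equal shape.
#' @return nonnegative loss.
#' @export
pixelLoss <- function(xt, xu) {
  if (is(xt, "MRImage")) xt <- xt@data
  if (is(xu, "MRImage")) xu <- xu@data
  if (!identical(dim(xt), dim(xu))) stop("shape mismatch")
  0.5 * mean((xt - xu)^2)
}

#' Frequency-domain content loss
#'
#' \code{1/2 * mean(|y_t - y_u|^2)} between the k-space representations of
#' the fully sampled image and the reconstruction (squared complex
#' magnitudes). With the package's orthonormal transform this equals the
#' pixel loss for real images (Parseval), and it is the term that pulls
#' the reconstruction toward k-space data consistency.
#'
#' @param yt,yu \linkS4class{KSpaceGrid}s (or complex matrices) of equal
#'   shape.
#' @return nonnegative loss.
#' @export
frequencyLoss <- function(yt, yu) {
  if (is(yt, "KSpaceGrid")) yt <- yt@data
  if (is(yu, "KSpaceGrid")) yu <- yu@data
  if (!identical(dim(yt), dim(yu))) stop("shape mismatch")
  0.5 * mean(Mod(yt - yu)^2)
}

#' Build a frozen random convolutional feature extractor
#'
#' A seeded, fixed (non-trainable) 3-layer strided convolutional feature
#' map used as the perceptual-loss extractor. Any deterministic
#' fixed-weight image-to-feature mapping satisfies the perceptual-loss
#' contract; a pretrained classifier's convolutional features can be
#' plugged in through the same interface.
#'
#' @param channels channel widths of the three layers.
#' @param kernel kernel side length.
#' @param seed integer seed for the frozen weights.
#' @return list of class "featureExtractor".
#' @export
makeFeatureExtractor <- function(channels = c(8, 8, 8), kernel = 3L, seed = 1L) {
  stopifnot(length(channels) == 3)
  cin <- c(1L, channels[1], channels[2])
  layers <- with_seed(seed, lapply(1:3, function(i) {
    fanIn <- kernel * kernel * cin[i]
    list(W = matrix(stats::rnorm(channels[i] * fanIn, sd = sqrt(2 / fanIn)),
                    channels[i], fanIn),
         b = rep(0, channels[i]), k = as.integer(kernel),
         cin = cin[i], cout = as.integer(channels[i]),
         stride = 2L, pad = as.integer((kernel - 1) %/% 2))
  }))
  structure(list(layers = layers, seed = as.integer(seed)),
            class = "featureExtractor")
}

## Apply the frozen extractor to one image matrix; returns feature array.
extractorForward <- function(extractor, x, withCache = FALSE) {
  a <- array(x, dim = c(nrow(x), ncol(x), 1L, 1L))
  caches <- list()
  for (ly in extractor$layers) {
    pre <- conv_fwd_cpp(a, ly$W, ly$b, ly$k, ly$stride, ly$pad)
    if (withCache) caches[[length(caches) + 1L]] <- list(x = a, pre = pre)
    a <- pre * (pre > 0) + 0.2 * pre * (pre <= 0)  # leaky ReLU 0.2
  }
  if (withCache) list(feat = a, caches = caches) else a
}

## Gradient of 1/2*mean((f(xt)-f(xu))^2) with respect to xu.
extractorBackward <- function(extractor, gfeat, caches) {
  g <- gfeat
  for (i in rev(seq_along(extractor$layers))) {
    ly <- extractor$layers[[i]]
    pre <- caches[[i]]$pre
    g <- g * ((pre > 0) + 0.2 * (pre <= 0))
    bw <- conv_bwd_cpp(caches[[i]]$x, ly$W, g, ly$k, ly$stride, ly$pad)
    g <- bw$gx
  }
  matrix(g, dim(g)[1], dim(g)[2])
}

#' Perceptual content loss
#'
#' \code{1/2 * mean((f(x_t) - f(x_u))^2)} under a fixed deterministic
#' feature extractor \code{f}. Pass \code{extractor = "identity"} to reduce
#' to the pixel loss.
#'
#' @param xt,xu matrices or \linkS4class{MRImage}s of equal shape.
#' @param extractor a \code{\link{makeFeatureExtractor}} object or
#'   "identity".
#' @return nonnegative loss.
#' @export
perceptualLoss <- function(xt, xu, extractor) {
  if (is(xt, "MRImage")) xt <- xt@data
  if (is(xu, "MRImage")) xu <- xu@data
  if (!identical(dim(xt), dim(xu))) stop("shape mismatch")
  if (identical(extractor, "identity")) return(pixelLoss(xt, xu))
  ft <- extractorForward(extractor, xt)
  fu <- extractorForward(extractor, xu)
  0.5 * mean((ft - fu)^2)
}

#' Loss weights for the combined generator objective
#'
#' @param alpha pixel-loss weight (published value 15).
#' @param beta frequency-loss weight (published value 0.1).
#' @param gammaPerc perceptual-loss weight (published value 0.0025); the
#'   adversarial weight is fixed at 1.
#' @return list of class "lossWeights".
#' @export
lossWeights <- function(alpha = 15, beta = 0.1, gammaPerc = 0.0025) {
  stopifnot(alpha >= 0, beta >= 0, gammaPerc >= 0)
  structure(list(alpha = alpha, beta = beta, gammaPerc = gammaPerc),
            class = "lossWeights")
}

#' Total generator loss
#'
#' \code{alpha * pixel + beta * frequency + gammaPerc * perceptual +
#' adversarial}.
#'
#' @param pixel,frequency,perceptual,adversarial finite loss components.
#' @param weights a \code{\link{lossWeights}} list.
#' @return the weighted total.
#' @export
totalGeneratorLoss <- function(pixel, frequency, perceptual, adversarial,
                               weights = lossWeights()) {
  stopifnot(is.finite(pixel), is.finite(frequency), is.finite(perceptual),
            is.finite(adversarial))
  weights$alpha * pixel + weights$beta * frequency +
    weights$gammaPerc * perceptual + adversarial
}
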
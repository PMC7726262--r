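## Adversarial optimization: Adam with gradient centralization, one
## discriminator step then one generator step per batch, per-epoch
## validation by NMSE, and best-model selection.

#' Optimizer configuration
#'
#' Published reference values: generator learning rate 1e-4, discriminator
#' 2e-4 (a 1:2 ratio so the two learn simultaneously), Adam moments
#' (0.5, 0.999), batch size 16, 30 epochs.
#'
#' @param lrGenerator,lrDiscriminator Adam learning rates (> 0).
#' @param beta1,beta2 Adam exponential decay rates, in [0, 1).
#' @param gradientCentralization center every weight-gradient slice to
#'   zero mean before the Adam update.
#' @param batchSize training batch size.
#' @param epochs training epochs.
#' @param seed integer seed driving batch shuffling.
#' @return list of class "optimizerConfig".
#' @export
optimizerConfig <- function(lrGenerator = 1e-4, lrDiscriminator = 2e-4,
                            beta1 = 0.5, beta2 = 0.999,
                            gradientCentralization = TRUE,
                            batchSize = 16L, epochs = 30L, seed = 1L) {
  stopifnot(lrGenerator > 0, lrDiscriminator > 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, batchSize >= 1)
  structure(list(lrGenerator = lrGenerator,
                 lrDiscriminator = lrDiscriminator,
                 beta1 = beta1, beta2 = beta2,
                 gradientCentralization = isTRUE(gradientCentralization),
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "optimizerConfig")
}

#' Centralize a weight gradient
#'
#' For weights with two or more dimensions, subtracts from each
#' output-unit slice (row of the flattened output-channels x rest matrix)
#' that slice's mean, so every returned slice has exactly zero mean.
#' Gradients of biases and scalars (fewer than 2 dimensions) pass through
#' unchanged.
#'
#' @param grad numeric array shaped like the weight.
#' @return centralized gradient of the same shape.
#' @export
centralizeGradient <- function(grad) {
  d <- dim(grad)
  if (is.null(d) || length(d) < 2) return(grad)
  m <- matrix(grad, d[1])
  m <- m - rowMeans(m)
  array(m, dim = d)
}

## ---- Adam over a parameter tree (driven by the gradient tree, so
## non-trainable fields like strides and SN vectors are untouched) ----

treeGet <- function(lst, key) {
  if (is.character(key)) {
    if (is.null(lst) || !key %in% names(lst)) NULL else lst[[key]]
  } else {
    if (is.null(lst) || length(lst) < key) NULL else lst[[key]]
  }
}

adamUpdateTree <- function(params, grads, m, v, lr, b1, b2, t, gc, eps = 1e-8) {
  keys <- if (!is.null(names(grads))) names(grads) else seq_along(grads)
  if (is.null(m)) m <- list()
  if (is.null(v)) v <- list()
  for (nm in keys) {
    g <- grads[[nm]]
    if (is.list(g)) {
      r <- adamUpdateTree(params[[nm]], g, treeGet(m, nm), treeGet(v, nm),
                          lr, b1, b2, t, gc, eps)
      params[[nm]] <- r$params; m[[nm]] <- r$m; v[[nm]] <- r$v
    } else {
      if (gc) g <- centralizeGradient(g)
      mm <- treeGet(m, nm); if (is.null(mm)) mm <- g * 0
      vv <- treeGet(v, nm); if (is.null(vv)) vv <- g * 0
      mm <- b1 * mm + (1 - b1) * g
      vv <- b2 * vv + (1 - b2) * g^2
      mhat <- mm / (1 - b1^t)
      vhat <- vv / (1 - b2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      m[[nm]] <- mm; v[[nm]] <- vv
    }
  }
  list(params = params, m = m, v = v)
}

bind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

sigmoid <- function(t) 1 / (1 + exp(-t))

## centered orthonormal FFT gradient of the frequency loss, one image
freqLossGrad <- function(xt, xu) {
  yd <- fftshift2(stats::fft(xu - xt)) / sqrt(length(xt))
  Re(stats::fft(ifftshift2(yd), inverse = TRUE)) / sqrt(length(xt)) / length(xt)
}

#' One adversarial training step
#'
#' Runs one discriminator update (relativistic average discriminator loss
#' on a half-real/half-fake minibatch scored with shared spectrally
#' normalized weights) followed by one generator update on the combined
#' objective (pixel + frequency + perceptual + relativistic adversarial).
#' Spectral-normalization power-iteration vectors advance once per
#' network per step; gradient centralization is applied to every weight
#' gradient when enabled.
#'
#' @param gen,disc current models.
#' @param z,x 4D (H, W, 1, N) arrays on [-1, 1]: zero-filled inputs and
#'   fully sampled targets.
#' @param state training state list (optimizer moments and step counter);
#'   pass \code{list()} at the first step.
#' @param opt an \code{\link{optimizerConfig}}.
#' @param weights a \code{\link{lossWeights}}.
#' @param extractor perceptual-loss extractor
#'   (\code{\link{makeFeatureExtractor}}) or NULL to skip the perceptual
#'   term.
#' @return list(gen, disc, state, losses) where losses holds lossD, lossG
#'   and the generator loss components.
#' @export
trainStep <- function(gen, disc, z, x, state, opt, weights = lossWeights(),
                      extractor = NULL) {
  stopifnot(length(dim(z)) == 4, dim(z)[4] >= 1)
  t <- (if (is.null(state$t)) 0L else state$t) + 1L
  nI <- dim(z)[4]
  hw <- dim(z)[1] * dim(z)[2]

  ## ---- discriminator update ----
  ## (train mode: batch-norm statistics and SN vectors advance here too)
  gfd <- genForwardCore(gen, z, train = TRUE)
  gen <- gfd$gen
  fake <- gfd$y
  df <- discForwardCore(disc, bind4(x, fake), train = TRUE)
  disc <- df$disc
  cr <- df$scores[seq_len(nI)]
  cf <- df$scores[nI + seq_len(nI)]
  lossD <- raDiscriminatorLoss(cr, cf)
  a <- cr - mean(cf); bvec <- cf - mean(cr)
  dLda <- -(1 - sigmoid(a)) / nI
  dLdb <- sigmoid(bvec) / nI
  gr <- dLda - mean(dLdb)
  gf <- dLdb - mean(dLda)
  dbw <- discBackwardCore(disc, df$caches, c(gr, gf))
  rD <- adamUpdateTree(disc@params, dbw$grads, state$mD, state$vD,
                       opt$lrDiscriminator, opt$beta1, opt$beta2, t,
                       opt$gradientCentralization)
  disc@params <- rD$params

  ## ---- generator update ----
  gfwd <- genForwardCore(gen, z, train = TRUE)
  gen <- gfwd$gen
  fake <- gfwd$y
  dfg <- discForwardCore(disc, bind4(x, fake), train = FALSE)
  cr <- dfg$scores[seq_len(nI)]
  cf <- dfg$scores[nI + seq_len(nI)]
  lossAdv <- raGeneratorLoss(cr, cf)
  a <- cr - mean(cf); bvec <- cf - mean(cr)
  dLdb <- -(1 - sigmoid(bvec)) / nI
  dLda <- sigmoid(a) / nI
  gsc_fake <- dLdb - mean(dLda)
  advBw <- discBackwardCore(disc, dfg$caches, c(rep(0, nI), gsc_fake))
  gAdv <- advBw$gx[, , , nI + seq_len(nI), drop = FALSE]

  lossPix <- 0.5 * mean((x - fake)^2)
  gPix <- (fake - x) / (hw * nI)
  lossFreq <- 0; gFreq <- array(0, dim = dim(fake))
  lossPerc <- 0; gPerc <- array(0, dim = dim(fake))
  for (n in seq_len(nI)) {
    xtm <- matrix(x[, , 1, n], dim(x)[1]); xum <- matrix(fake[, , 1, n], dim(x)[1])
    lossFreq <- lossFreq + frequencyLoss(forwardTransform(xtm)@data,
                                         forwardTransform(xum)@data) / nI
    gFreq[, , 1, n] <- freqLossGrad(xtm, xum) / nI
    if (!is.null(extractor)) {
      et <- extractorForward(extractor, xtm)
      eu <- extractorForward(extractor, xum, withCache = TRUE)
      lossPerc <- lossPerc + 0.5 * mean((et - eu$feat)^2) / nI
      gPerc[, , 1, n] <- extractorBackward(extractor,
                                           (eu$feat - et) / length(et),
                                           eu$caches) / nI
    }
  }
  gTotal <- weights$alpha * gPix + weights$beta * gFreq +
    weights$gammaPerc * gPerc + gAdv
  gbw <- genBackwardCore(gen, gfwd$caches, gTotal)
  rG <- adamUpdateTree(gen@params, gbw$grads, state$mG, state$vG,
                       opt$lrGenerator, opt$beta1, opt$beta2, t,
                       opt$gradientCentralization)
  gen@params <- rG$params

  lossG <- totalGeneratorLoss(lossPix, lossFreq, lossPerc, lossAdv, weights)
  if (!is.finite(lossD) || !is.finite(lossG))
    stop("non-finite loss at step ", t, ": lossD=", lossD, " lossG=", lossG)
  state$t <- t
  state$mD <- rD$m; state$vD <- rD$v
  state$mG <- rG$m; state$vG <- rG$v
  list(gen = gen, disc = disc, state = state,
       losses = list(lossD = lossD, lossG = lossG, pixel = lossPix,
                     frequency = lossFreq, perceptual = lossPerc,
                     adversarial = lossAdv))
}

## Images -> network-scale arrays, pairing each full image with its
## zero-filled version under a fixed mask.
imagesToArrays <- function(images, mask) {
  h <- nrow(images[[1]]@data); w <- ncol(images[[1]]@data)
  n <- length(images)
  x <- array(0, dim = c(h, w, 1L, n))
  z <- array(0, dim = c(h, w, 1L, n))
  for (i in seq_len(n)) {
    im <- images[[i]]
    r <- im@intensityRange
    x[, , 1, i] <- (im@data - r[1]) / (r[2] - r[1]) * 2 - 1
    zf <- zeroFilledRecon(im, mask)
    z[, , 1, i] <- pmin(pmax((zf@data - r[1]) / (r[2] - r[1]) * 2 - 1, -1), 1)
  }
  list(x = x, z = z)
}

#' Mean validation NMSE of a generator
#'
#' Undersamples every validation image with the given mask, reconstructs,
#' and averages \code{\link{nmse}} against the fully sampled reference.
#'
#' @param gen a \linkS4class{ReconGenerator}, or "identity" for the
#'   zero-filled baseline, or "oracle" for a perfect model.
#' @param images non-empty list of \linkS4class{MRImage}.
#' @param mask a \linkS4class{SamplingMask}.
#' @return mean NMSE over the split.
#' @export
validateNmse <- function(gen, images, mask) {
  if (length(images) == 0) stop("empty validation split")
  vals <- vapply(images, function(im) {
    zf <- zeroFilledRecon(im, mask)
    rec <- if (identical(gen, "identity")) zf
      else if (identical(gen, "oracle")) im
      else reconstructImage(gen, zf)
    nmse(im, rec)
  }, numeric(1))
  mean(vals)
}

#' Train the reconstruction model
#'
#' Full adversarial training: per batch one discriminator update then one
#' generator update; after each epoch the mean validation NMSE is
#' computed and the checkpoint with the smallest value so far is kept
#' (ties keep the earlier epoch). With \code{epochs = 0} the initialized
#' (identity) generator is returned with its baseline validation NMSE.
#'
#' @param dataset a \code{\link{makeDataset}} result (or any list with
#'   \code{train} and \code{val} lists of \linkS4class{MRImage}).
#' @param mask the \linkS4class{SamplingMask} defining the acquisition.
#' @param genConfig,discConfig network configurations.
#' @param opt an \code{\link{optimizerConfig}}.
#' @param weights a \code{\link{lossWeights}}.
#' @param extractor perceptual extractor or NULL.
#' @param historyCsv optional CSV path for the per-step loss history.
#' @param verbose print per-epoch progress.
#' @return list of class "trainResult": \code{gen} (best checkpoint),
#'   \code{finalGen}, \code{disc}, \code{history} (one row per step),
#'   \code{valNmse} (per epoch), \code{bestEpoch}, \code{bestValNmse},
#'   \code{baselineNmse} (zero-filled validation NMSE).
#' @export
fitModel <- function(dataset, mask, genConfig = generatorConfig(),
                     discConfig = discriminatorConfig(),
                     opt = optimizerConfig(), weights = lossWeights(),
                     extractor = NULL, historyCsv = NULL, verbose = FALSE) {
  stopifnot(length(dataset$train) >= 1, length(dataset$val) >= 1)
  h <- nrow(dataset$train[[1]]@data)
  gen <- buildGenerator(genConfig)
  disc <- buildDiscriminator(discConfig, inputSize = h)
  tr <- imagesToArrays(dataset$train, mask)
  baselineNmse <- validateNmse("identity", dataset$val, mask)
  bestNmse <- validateNmse(gen, dataset$val, mask)
  bestGen <- gen
  bestEpoch <- 0L
  valNmse <- numeric(0)
  state <- list()
  history <- list()
  nTrain <- dim(tr$x)[4]
  for (epoch in seq_len(opt$epochs)) {
    ord <- with_seed(opt$seed + epoch, sample.int(nTrain))
    starts <- seq(1, nTrain, by = opt$batchSize)
    for (si in seq_along(starts)) {
      idx <- ord[starts[si]:min(starts[si] + opt$batchSize - 1L, nTrain)]
      st <- trainStep(gen, disc,
                      tr$z[, , , idx, drop = FALSE],
                      tr$x[, , , idx, drop = FALSE],
                      state, opt, weights, extractor)
      gen <- st$gen; disc <- st$disc; state <- st$state
      history[[length(history) + 1L]] <- data.frame(
        epoch = epoch, step = state$t, lossD = st$losses$lossD,
        lossG = st$losses$lossG, pixel = st$losses$pixel,
        frequency = st$losses$frequency, perceptual = st$losses$perceptual,
        adversarial = st$losses$adversarial)
    }
    vn <- validateNmse(gen, dataset$val, mask)
    valNmse <- c(valNmse, vn)
    if (vn < bestNmse) {
      bestNmse <- vn; bestGen <- gen; bestEpoch <- epoch
    }
    if (verbose)
      message(sprintf("epoch %d: val NMSE %.5f (best %.5f @ %d, zero-filled %.5f)",
                      epoch, vn, bestNmse, bestEpoch, baselineNmse))
  }
  history <- if (length(history)) do.call(rbind, history) else
    data.frame(epoch = integer(0), step = integer(0), lossD = numeric(0),
               lossG = numeric(0), pixel = numeric(0), frequency = numeric(0),
               perceptual = numeric(0), adversarial = numeric(0))
  if (!is.null(historyCsv)) utils::write.csv(history, historyCsv, row.names = FALSE)
  structure(list(gen = bestGen, finalGen = gen, disc = disc,
                 history = history, valNmse = valNmse,
                 bestEpoch = bestEpoch, bestValNmse = bestNmse,
                 baselineNmse = baselineNmse),
            class = "trainResult")
}

#' Desk-scale training preset
#'
#' A configuration that trains end-to-end on one CPU in minutes: 64 x 64
#' phantoms, generator base 16 channels, discriminator base 8, batch 4,
#' 5 epochs. The generator learning rate is scaled up tenfold from the
#' reference value because the schedule is roughly two orders of magnitude
#' shorter; the discriminator stays at its reference pace (it would
#' otherwise win within the first epoch and its saturated feedback would
#' drown the content losses before the generator has learned anything).
#'
#' @param seed master seed.
#' @return list with elements genConfig, discConfig, opt, weights,
#'   phantom (a \code{\link{phantomSpec}}), nTrain, nVal, nTest,
#'   maskPattern, maskRate.
#' @export
deskScaleConfig <- function(seed = 1L) {
  list(genConfig = generatorConfig(baseChannels = 16L, seed = seed),
       discConfig = discriminatorConfig(baseChannels = 8L, seed = seed + 1L),
       opt = optimizerConfig(lrGenerator = 1e-3, lrDiscriminator = 1e-4,
                             batchSize = 4L, epochs = 5L, seed = seed + 2L),
       weights = lossWeights(),
       phantom = phantomSpec(height = 64L, width = 64L, seed = seed),
       nTrain = 200L, nVal = 50L, nTest = 50L,
       maskPattern = "gaussian1d", maskRate = 0.10)
}
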
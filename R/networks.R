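## Generator (3 strided down-sampling convolutions, 7 residual blocks, a
## self-attention module, 3 transposed-convolution up-sampling layers,
## PReLU activations, spectral normalization, learnable global residual
## blend) and the 11-layer convolutional discriminator emitting a raw
## score C(.). Forward and backward passes are written against the Rcpp
## im2col kernels; gradients are exact, including through the spectral
## normalization.

#' Generator configuration
#'
#' @param baseChannels channel width of the first down-sampling layer; the
#'   plan is base -> 2x -> 4x down, residual blocks at 4x, mirrored up.
#' @param downLayers,upLayers stride-2 layer counts (3 in reference mode).
#' @param residualBlocks residual block count (7 in reference mode), two
#'   convolutions per block with an internal skip connection.
#' @param kernel convolution kernel side (3).
#' @param attentionLayerIndex where the self-attention module sits in the
#'   up-sampling block: 0 = on its input (the last residual block's output,
#'   the lowest resolution), i = after the i-th transposed convolution.
#' @param useAttention,useSpectralNorm ablation switches (disabling
#'   attention gives the relativistic-average-only variant; disabling
#'   spectral normalization gives the no-SN variant).
#' @param preluInit initial PReLU negative slope.
#' @param seed integer seed; builds are bitwise-reproducible.
#' @return list of class "generatorConfig".
#' @export
generatorConfig <- function(baseChannels = 64L, downLayers = 3L,
                            residualBlocks = 7L, upLayers = 3L, kernel = 3L,
                            attentionLayerIndex = 0L, useAttention = TRUE,
                            useSpectralNorm = TRUE, preluInit = 0.25,
                            seed = 1L) {
  if (downLayers != upLayers) stop("config error: down/up layer counts must match")
  if (downLayers < 1 || residualBlocks < 1) stop("config error: invalid layer counts")
  if (attentionLayerIndex < 0 || attentionLayerIndex > upLayers)
    stop("config error: attentionLayerIndex out of range")
  structure(list(baseChannels = as.integer(baseChannels),
                 downLayers = as.integer(downLayers),
                 residualBlocks = as.integer(residualBlocks),
                 upLayers = as.integer(upLayers), kernel = as.integer(kernel),
                 attentionLayerIndex = as.integer(attentionLayerIndex),
                 useAttention = isTRUE(useAttention),
                 useSpectralNorm = isTRUE(useSpectralNorm),
                 preluInit = preluInit, seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Discriminator configuration
#'
#' @param baseChannels width of the first convolution; widths double at
#'   each stride-2 layer, capped at 8x.
#' @param convLayers convolution count (11 in reference mode), strides
#'   alternating 1/2.
#' @param leakySlope leaky-ReLU negative slope.
#' @param useSpectralNorm ablation switch.
#' @param kernel kernel side.
#' @param seed integer seed.
#' @return list of class "discriminatorConfig".
#' @export
discriminatorConfig <- function(baseChannels = 64L, convLayers = 11L,
                                leakySlope = 0.2, useSpectralNorm = TRUE,
                                kernel = 3L, seed = 1L) {
  if (convLayers < 1) stop("config error: convLayers must be >= 1")
  structure(list(baseChannels = as.integer(baseChannels),
                 convLayers = as.integer(convLayers),
                 leakySlope = leakySlope,
                 useSpectralNorm = isTRUE(useSpectralNorm),
                 kernel = as.integer(kernel), seed = as.integer(seed)),
            class = "discriminatorConfig")
}

#' @export
setClass("ReconGenerator", representation(config = "ANY", params = "list"))

#' @export
setClass("ReconDiscriminator", representation(config = "ANY", params = "list"))

countLeaves <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (!is.list(x)) return(0)
  sum(vapply(x, countLeaves, numeric(1)))
}

setMethod("show", "ReconGenerator", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ReconGenerator: %d down / %d residual / %d up, base %d channels, %s attention, %s spectral norm, %d parameters\n",
    cfg$downLayers, cfg$residualBlocks, cfg$upLayers, cfg$baseChannels,
    if (cfg$useAttention) "with" else "no",
    if (cfg$useSpectralNorm) "with" else "no",
    countLeaves(object@params)))
})

setMethod("show", "ReconDiscriminator", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ReconDiscriminator: %d conv layers, base %d channels, leaky slope %g, %s spectral norm, %d parameters\n",
    cfg$convLayers, cfg$baseChannels, cfg$leakySlope,
    if (cfg$useSpectralNorm) "with" else "no", countLeaves(object@params)))
})

## He-initialized conv layer; weight flattened (cout x k*k*cin), SN vector
## u seeded separately per layer.
## Largest singular value (exact, build time only).
norm2 <- function(W) svd(W, nu = 0, nv = 0)$d[1]

## Seeded standard-normal u, burnt in by power iterations at build time so
## the per-step single iteration starts converged.
snBurnIn <- function(W, iters = 50L) {
  u <- stats::rnorm(nrow(W))
  u <- u / sqrt(sum(u^2))
  for (i in seq_len(iters)) {
    v <- drop(crossprod(W, u)); v <- v / sqrt(sum(v^2))
    u <- drop(W %*% v); u <- u / sqrt(sum(u^2))
  }
  u
}

newConvLayer <- function(cin, cout, k, stride, act, preluInit = 0.25,
                         transposed = FALSE, initScale = 1, bn = FALSE,
                         gain = TRUE) {
  fanIn <- k * k * cin
  if (transposed) {
    # adjoint-convolution orientation: (cin x k*k*cout)
    W <- matrix(stats::rnorm(cin * k * k * cout, sd = sqrt(2 / fanIn)),
                cin, k * k * cout)
  } else {
    W <- matrix(stats::rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), cout, fanIn)
  }
  W <- W * initScale
  u <- snBurnIn(W)
  ly <- list(W = W, b = rep(0, cout), k = as.integer(k),
             stride = as.integer(stride), pad = as.integer((k - 1) %/% 2),
             cin = as.integer(cin), cout = as.integer(cout), act = act,
             transposed = transposed, u = u)
  if (gain) ly$gain <- norm2(W)
  if (act == "prelu") ly$alpha <- rep(preluInit, cout)
  if (bn) {
    ly$bnGamma <- rep(1, cout)
    ly$bnBeta <- rep(0, cout)
    ly$runMean <- rep(0, cout)
    ly$runVar <- rep(1, cout)
  }
  ly
}

## Per-channel batch normalization on a (H, W, C, N) array.
bnFwd <- function(pre, ly, train, eps = 1e-5) {
  d <- dim(pre)
  m <- matrix(aperm(pre, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
  if (train) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
  } else {
    mu <- ly$runMean
    va <- ly$runVar
  }
  xhat <- sweep(sweep(m, 2, mu), 2, sqrt(va + eps), "/")
  out <- sweep(sweep(xhat, 2, ly$bnGamma, "*"), 2, ly$bnBeta, "+")
  list(y = aperm(array(out, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)),
       cache = list(xhat = xhat, istd = 1 / sqrt(va + eps), d = d,
                    mu = mu, va = va))
}

bnBwd <- function(gy, ly, cache) {
  d <- cache$d
  gm <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
  gbeta <- colSums(gm)
  ggamma <- colSums(gm * cache$xhat)
  gxhat <- sweep(gm, 2, ly$bnGamma, "*")
  M <- nrow(gm)
  gx <- sweep(gxhat - matrix(colMeans(gxhat), M, d[3], byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), "*"),
              2, cache$istd, "*")
  list(gx = aperm(array(gx, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)),
       ggamma = ggamma, gbeta = gbeta)
}

#' Build the de-aliasing generator
#'
#' Constructs the image-to-image network: stride-2 down-sampling
#' convolutions (channels base, 2x, 4x), \code{residualBlocks} residual
#' blocks (output = input + conv(PReLU(conv(input)))), the self-attention
#' module, and mirrored transposed-convolution up-sampling back to one
#' channel, whose final read-out layer is initialized two orders of
#' magnitude small. The output is a global residual connection
#' \code{clip(input + blend * correction, -1, 1)} with a learnable blend
#' coefficient, so a freshly built generator starts (up to the tiny
#' read-out) at the identity on its zero-filled input, which stabilizes
#' the early adversarial phase. When spectral normalization is enabled,
#' every weight is used as \code{gain * W / sigma(W)} with a learnable
#' scalar gain initialized to the He-init weight's spectral norm: the
#' network starts exactly as its unnormalized counterpart while the
#' weight direction stays spectrally smoothed.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a \linkS4class{ReconGenerator} with seeded, bitwise-reproducible
#'   parameters.
#' @export
buildGenerator <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  b <- config$baseChannels; k <- config$kernel
  with_seed(config$seed, {
    downCh <- b * 2^(seq_len(config$downLayers) - 1)
    down <- list()
    cin <- 1L
    for (i in seq_len(config$downLayers)) {
      down[[i]] <- newConvLayer(cin, downCh[i], k, 2L, "prelu", config$preluInit,
                                bn = TRUE)
      cin <- downCh[i]
    }
    res <- lapply(seq_len(config$residualBlocks), function(i) {
      list(c1 = newConvLayer(cin, cin, k, 1L, "prelu", config$preluInit,
                             bn = TRUE),
           c2 = newConvLayer(cin, cin, k, 1L, "linear", bn = TRUE))
    })
    upCh <- c(rev(downCh)[-1], 1L)
    up <- list()
    ucin <- cin
    for (i in seq_len(config$upLayers)) {
      act <- if (i < config$upLayers) "prelu" else "linear"
      # final read-out initialized small and un-normalized: the generator
      # starts near the identity on its zero-filled input
      last <- i == config$upLayers
      up[[i]] <- newConvLayer(ucin, upCh[i], k, 2L, act, config$preluInit,
                              transposed = TRUE,
                              initScale = if (last) 0.01 else 1,
                              bn = !last)
      ucin <- upCh[i]
    }
    params <- list(down = down, res = res, up = up, blend = 1)
    if (config$useAttention) {
      attnCh <- if (config$attentionLayerIndex == 0L) cin
        else upCh[config$attentionLayerIndex]
      if (attnCh %% 8 != 0)
        stop("config error: attention site has ", attnCh,
             " channels, not divisible by 8")
      params$attn <- initAttentionParams(attnCh, seed = config$seed + 104729L)
      # persistent power-iteration vectors + gains for the 1x1 projections
      for (nm in c("Wf", "Wg", "Wh", "Wv")) {
        params$attn[[paste0("u", nm)]] <- snBurnIn(params$attn[[nm]])
        params$attn[[paste0("gain", nm)]] <- norm2(params$attn[[nm]])
      }
    }
    new("ReconGenerator", config = config, params = params)
  })
}

#' Build the discriminator
#'
#' An \code{convLayers}-deep CNN with strides alternating 1/2, leaky-ReLU
#' activations, spectral normalization on every weight, and a final dense
#' layer producing one raw (pre-sigmoid) score per image: the relativistic
#' sigmoid is applied by the loss, not the network.
#'
#' @param config a \code{\link{discriminatorConfig}}.
#' @param inputSize spatial side length the discriminator will see (needed
#'   to size the dense layer).
#' @return a \linkS4class{ReconDiscriminator}.
#' @export
buildDiscriminator <- function(config, inputSize = 64L) {
  stopifnot(inherits(config, "discriminatorConfig"))
  d <- config$baseChannels; k <- config$kernel
  with_seed(config$seed, {
    layers <- list()
    cin <- 1L; ch <- d; sz <- as.integer(inputSize)
    strides <- rep_len(c(1L, 2L), config$convLayers)
    for (i in seq_len(config$convLayers)) {
      # pure spectral normalization (no learnable gain): each layer is
      # 1-Lipschitz, which is what keeps adversarial feedback bounded
      layers[[i]] <- newConvLayer(cin, ch, k, strides[i], "lrelu",
                                  gain = FALSE)
      cin <- ch
      if (strides[i] == 2L) {
        sz <- as.integer((sz + 2 * ((k - 1) %/% 2) - k) / 2 + 1)
        ch <- min(ch * 2L, 8L * d)
      }
    }
    featDim <- sz * sz * cin
    Wd <- matrix(stats::rnorm(featDim, sd = sqrt(1 / featDim)), 1, featDim)
    params <- list(convs = layers,
                   dense = list(W = Wd, b = 0, u = snBurnIn(Wd)),
                   inputSize = as.integer(inputSize))
    new("ReconDiscriminator", config = config, params = params)
  })
}

## ---- spectral normalization plumbing ----

## One power iteration from the layer's persistent u; returns Wbar and the
## quantities the backward pass needs.
snApply <- function(W, u, enabled, nIter = 1L) {
  if (!enabled) return(list(Wbar = W, sigma = 1, u = u, v = NULL))
  est <- estimateSigma(W, structure(list(u = u, nPowerIterations = nIter),
                                    class = "spectralState"))
  list(Wbar = W / est$sigma, sigma = est$sigma, u = est$state$u, v = est$v)
}

## Gradient through W -> W/sigma(W) with sigma = u' W v:
## gW = (gWbar - sum(gWbar * Wbar) * u v') / sigma.
snBackward <- function(gWbar, sn) {
  if (is.null(sn$v)) return(gWbar)
  (gWbar - sum(gWbar * sn$Wbar) * (sn$u %o% sn$v)) / sn$sigma
}

## ---- activations on 4D arrays ----

alphaArray <- function(alpha, d) array(rep(alpha, each = d[1] * d[2]), dim = d)

actFwd <- function(pre, act, alpha = NULL, slope = 0.2) {
  switch(act,
    linear = pre,
    lrelu = pre * (pre > 0) + slope * pre * (pre <= 0),
    prelu = {
      am <- alphaArray(alpha, dim(pre))
      pre * (pre > 0) + am * pre * (pre <= 0)
    })
}

actBwd <- function(gy, pre, act, alpha = NULL, slope = 0.2) {
  switch(act,
    linear = list(gpre = gy),
    lrelu = list(gpre = gy * ((pre > 0) + slope * (pre <= 0))),
    prelu = {
      am <- alphaArray(alpha, dim(pre))
      neg <- pre <= 0
      galpha <- apply(gy * pre * neg, 3, sum)
      list(gpre = gy * ((pre > 0) + am * neg), galpha = galpha)
    })
}

## ---- conv / tconv layer forward+backward ----

## Effective weight: spectrally normalized direction times the learnable
## scalar gain. The gain is initialized to the He-init weight's spectral
## norm, so at build time the effective weight equals the raw one: signal
## propagation starts healthy while SN keeps the direction smooth.
layerFwd <- function(ly, x, useSN, slope = 0.2, nIter = 1L, train = FALSE) {
  sn <- snApply(ly$W, ly$u, useSN, nIter)
  Weff <- if (!useSN) ly$W
    else if (is.null(ly$gain)) sn$Wbar
    else ly$gain * sn$Wbar
  if (ly$transposed) {
    d <- dim(x)
    pre <- tconv_fwd_cpp(x, Weff, ly$b, ly$k, ly$stride, ly$pad,
                         d[1] * ly$stride, d[2] * ly$stride)
  } else {
    pre <- conv_fwd_cpp(x, Weff, ly$b, ly$k, ly$stride, ly$pad)
  }
  cache <- list(x = x, sn = sn, Weff = Weff)
  if (!is.null(ly$bnGamma)) {
    bf <- bnFwd(pre, ly, train)
    cache$bn <- bf$cache
    if (train) {
      cache$runMean <- 0.9 * ly$runMean + 0.1 * bf$cache$mu
      cache$runVar <- 0.9 * ly$runVar + 0.1 * bf$cache$va
    }
    pre <- bf$y
  }
  cache$pre <- pre
  y <- actFwd(pre, ly$act, ly$alpha, slope)
  list(y = y, cache = cache)
}

layerBwd <- function(ly, cache, gy, useSN, slope = 0.2) {
  ab <- actBwd(gy, cache$pre, ly$act, ly$alpha, slope)
  gpre <- ab$gpre
  bngrads <- NULL
  if (!is.null(ly$bnGamma)) {
    bb <- bnBwd(gpre, ly, cache$bn)
    bngrads <- list(bnGamma = bb$ggamma, bnBeta = bb$gbeta)
    gpre <- bb$gx
  }
  bw <- if (ly$transposed)
    tconv_bwd_cpp(cache$x, cache$Weff, gpre, ly$k, ly$stride, ly$pad)
  else
    conv_bwd_cpp(cache$x, cache$Weff, gpre, ly$k, ly$stride, ly$pad)
  if (useSN && !is.null(ly$gain)) {
    grads <- list(W = snBackward(ly$gain * bw$gW, cache$sn),
                  b = as.numeric(bw$gb),
                  gain = sum(bw$gW * cache$sn$Wbar))
  } else if (useSN) {
    grads <- list(W = snBackward(bw$gW, cache$sn), b = as.numeric(bw$gb))
  } else {
    grads <- list(W = bw$gW, b = as.numeric(bw$gb))
  }
  if (ly$act == "prelu") grads$alpha <- ab$galpha
  if (!is.null(bngrads)) grads <- c(grads, bngrads)
  list(gx = bw$gx, grads = grads)
}

## ---- generator forward / backward ----

## x: (H, W, 1, N) array on [-1, 1]. Returns output, caches for backward,
## and (when train = TRUE) the updated SN vectors.
genForwardCore <- function(gen, x, train = FALSE) {
  cfg <- gen@config; p <- gen@params
  useSN <- cfg$useSpectralNorm
  caches <- list(down = list(), res = list(), up = list())
  persist <- function(ly, cache) {
    ly$u <- cache$sn$u
    if (!is.null(cache$runMean)) {
      ly$runMean <- cache$runMean
      ly$runVar <- cache$runVar
    }
    ly
  }
  h <- x
  for (i in seq_along(p$down)) {
    f <- layerFwd(p$down[[i]], h, useSN, train = train)
    caches$down[[i]] <- f$cache
    if (train) p$down[[i]] <- persist(p$down[[i]], f$cache)
    h <- f$y
  }
  for (i in seq_along(p$res)) {
    f1 <- layerFwd(p$res[[i]]$c1, h, useSN, train = train)
    f2 <- layerFwd(p$res[[i]]$c2, f1$y, useSN, train = train)
    caches$res[[i]] <- list(c1 = f1$cache, c2 = f2$cache)
    if (train) {
      p$res[[i]]$c1 <- persist(p$res[[i]]$c1, f1$cache)
      p$res[[i]]$c2 <- persist(p$res[[i]]$c2, f2$cache)
    }
    h <- h + f2$y
  }
  attnAt <- function(idx) cfg$useAttention && cfg$attentionLayerIndex == idx
  apEff <- p$attn
  if (cfg$useAttention && useSN) {
    attnSN <- list()
    for (nm in c("Wf", "Wg", "Wh", "Wv")) {
      attnSN[[nm]] <- snApply(p$attn[[nm]], p$attn[[paste0("u", nm)]], TRUE)
      apEff[[nm]] <- p$attn[[paste0("gain", nm)]] * attnSN[[nm]]$Wbar
      if (train) p$attn[[paste0("u", nm)]] <- attnSN[[nm]]$u
    }
    caches$attnSN <- attnSN
  }
  caches$apEff <- apEff
  runAttn <- function(h) {
    d <- dim(h)
    ys <- vector("list", d[4]); cs <- vector("list", d[4])
    for (n in seq_len(d[4])) {
      fc <- attnFwdCache(array(h[, , , n], d[1:3]), apEff)
      ys[[n]] <- fc$y; cs[[n]] <- fc$cache
    }
    list(y = array(unlist(ys), dim = d), caches = cs)
  }
  if (attnAt(0L)) {
    a <- runAttn(h)
    caches$attn <- a$caches
    h <- a$y
  }
  for (i in seq_along(p$up)) {
    f <- layerFwd(p$up[[i]], h, useSN, train = train)
    caches$up[[i]] <- f$cache
    if (train) p$up[[i]] <- persist(p$up[[i]], f$cache)
    h <- f$y
    if (attnAt(i)) {
      a <- runAttn(h)
      caches$attn <- a$caches
      h <- a$y
    }
  }
  raw <- x + p$blend * h
  y <- pmin(pmax(raw, -1), 1)
  caches$correction <- h
  caches$raw <- raw
  caches$input <- x
  gen@params <- p
  list(y = y, caches = caches, gen = gen)
}

## gy: gradient at the clipped output. Returns parameter gradients (same
## tree shape as params) and optionally the input gradient.
genBackwardCore <- function(gen, caches, gy) {
  cfg <- gen@config; p <- gen@params
  useSN <- cfg$useSpectralNorm
  inside <- (caches$raw > -1) & (caches$raw < 1)
  graw <- gy * inside
  gblend <- sum(graw * caches$correction)
  g <- p$blend * graw
  grads <- list(down = vector("list", length(p$down)),
                res = vector("list", length(p$res)),
                up = vector("list", length(p$up)),
                blend = gblend)
  attnAt <- function(idx) cfg$useAttention && cfg$attentionLayerIndex == idx
  backAttn <- function(g) {
    d <- dim(g)
    gxs <- vector("list", d[4])
    agr <- NULL
    for (n in seq_len(d[4])) {
      bw <- attnBwd(array(g[, , , n], d[1:3]), caches$apEff, caches$attn[[n]])
      gxs[[n]] <- bw$gx
      agr <- if (is.null(agr)) bw$grads else Map(`+`, agr, bw$grads)
    }
    if (useSN) {
      for (nm in c("Wf", "Wg", "Wh", "Wv")) {
        agr[[paste0("gain", nm)]] <- sum(agr[[nm]] * caches$attnSN[[nm]]$Wbar)
        agr[[nm]] <- snBackward(p$attn[[paste0("gain", nm)]] * agr[[nm]],
                                caches$attnSN[[nm]])
      }
    }
    list(gx = array(unlist(gxs), dim = d), grads = agr)
  }
  for (i in rev(seq_along(p$up))) {
    if (attnAt(i)) {
      ab <- backAttn(g)
      grads$attn <- ab$grads
      g <- ab$gx
    }
    bw <- layerBwd(p$up[[i]], caches$up[[i]], g, useSN)
    grads$up[[i]] <- bw$grads
    g <- bw$gx
  }
  if (attnAt(0L)) {
    ab <- backAttn(g)
    grads$attn <- ab$grads
    g <- ab$gx
  }
  for (i in rev(seq_along(p$res))) {
    bw2 <- layerBwd(p$res[[i]]$c2, caches$res[[i]]$c2, g, useSN)
    bw1 <- layerBwd(p$res[[i]]$c1, caches$res[[i]]$c1, bw2$gx, useSN)
    grads$res[[i]] <- list(c1 = bw1$grads, c2 = bw2$grads)
    g <- g + bw1$gx
  }
  for (i in rev(seq_along(p$down))) {
    bw <- layerBwd(p$down[[i]], caches$down[[i]], g, useSN)
    grads$down[[i]] <- bw$grads
    g <- bw$gx
  }
  list(grads = grads, gx = g)
}

#' Run the generator on zero-filled input
#'
#' Accepts a single \linkS4class{MRImage} (any declared range; rescaled to
#' the network's [-1, 1] internally and back on output), a numeric matrix
#' already on [-1, 1], or a 4D (H, W, 1, N) batch array on [-1, 1].
#' Deterministic: repeated calls give identical output and do not advance
#' any internal state.
#'
#' @param gen a \linkS4class{ReconGenerator}.
#' @param x input image(s); see above.
#' @return reconstruction of the same kind as the input.
#' @export
generatorForward <- function(gen, x) {
  stopifnot(is(gen, "ReconGenerator"))
  if (is(x, "MRImage")) return(reconstructImage(gen, x))
  if (is.matrix(x)) {
    a <- array(x, dim = c(nrow(x), ncol(x), 1L, 1L))
    if (any(!is.finite(a))) stop("non-finite input")
    return(matrix(genForwardCore(gen, a)$y, nrow(x), ncol(x)))
  }
  if (any(!is.finite(x))) stop("non-finite input")
  genForwardCore(gen, x)$y
}

#' Reconstruct an image from its zero-filled version
#'
#' Rescales the image from its declared intensity range to the network's
#' [-1, 1], runs the generator, and maps the output back.
#'
#' @param gen a \linkS4class{ReconGenerator}.
#' @param zeroFilled an \linkS4class{MRImage} (typically from
#'   \code{\link{zeroFilledRecon}}).
#' @return an \linkS4class{MRImage} on the same declared range.
#' @export
reconstructImage <- function(gen, zeroFilled) {
  stopifnot(is(gen, "ReconGenerator"), is(zeroFilled, "MRImage"))
  r <- zeroFilled@intensityRange
  z <- (zeroFilled@data - r[1]) / (r[2] - r[1]) * 2 - 1
  z <- pmin(pmax(z, -1), 1)
  y <- generatorForward(gen, z)
  MRImage((y + 1) / 2 * (r[2] - r[1]) + r[1], r)
}

## ---- discriminator forward / backward ----

discForwardCore <- function(disc, x, train = FALSE) {
  cfg <- disc@config; p <- disc@params
  useSN <- cfg$useSpectralNorm
  caches <- list(convs = list())
  h <- x
  for (i in seq_along(p$convs)) {
    f <- layerFwd(p$convs[[i]], h, useSN, slope = cfg$leakySlope)
    caches$convs[[i]] <- f$cache
    if (train) p$convs[[i]]$u <- f$cache$sn$u
    h <- f$y
  }
  d <- dim(h)
  feat <- matrix(h, d[1] * d[2] * d[3], d[4])   # featDim x N
  snD <- snApply(p$dense$W, p$dense$u, useSN)
  if (train) p$dense$u <- snD$u
  WdEff <- if (useSN) snD$Wbar else p$dense$W
  scores <- as.numeric(WdEff %*% feat + p$dense$b)
  caches$feat <- feat
  caches$featDim <- d
  caches$snD <- snD
  caches$WdEff <- WdEff
  disc@params <- p
  list(scores = scores, caches = caches, disc = disc)
}

discBackwardCore <- function(disc, caches, gscores) {
  cfg <- disc@config; p <- disc@params
  useSN <- cfg$useSpectralNorm
  gWdEff <- matrix(gscores, 1) %*% t(caches$feat)
  gfeat <- t(caches$WdEff) %*% matrix(gscores, 1)   # featDim x N
  g <- array(gfeat, dim = caches$featDim)
  dense <- if (useSN)
    list(W = snBackward(gWdEff, caches$snD), b = sum(gscores))
  else list(W = gWdEff, b = sum(gscores))
  grads <- list(convs = vector("list", length(p$convs)), dense = dense)
  for (i in rev(seq_along(p$convs))) {
    bw <- layerBwd(p$convs[[i]], caches$convs[[i]], g, useSN,
                   slope = cfg$leakySlope)
    grads$convs[[i]] <- bw$grads
    g <- bw$gx
  }
  list(grads = grads, gx = g)
}

#' Raw discriminator scores
#'
#' One finite real score per image, before any sigmoid: the relativistic
#' average losses apply their sigmoid to score differences.
#'
#' @param disc a \linkS4class{ReconDiscriminator}.
#' @param x a matrix on [-1, 1] or a 4D (H, W, 1, N) batch array.
#' @return numeric vector of N scores.
#' @export
discriminatorScore <- function(disc, x) {
  stopifnot(is(disc, "ReconDiscriminator"))
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L, 1L))
  if (any(!is.finite(x))) stop("non-finite input")
  discForwardCore(disc, x)$scores
}

## ---- checkpoints ----

#' Save a model checkpoint
#'
#' Writes the parameter tree (including spectral-normalization vectors) as
#' an RDS archive with a version tag, plus a JSON snapshot of the config
#' alongside it.
#'
#' @param model a \linkS4class{ReconGenerator} or
#'   \linkS4class{ReconDiscriminator}.
#' @param path output file path (".rds" recommended).
#' @return the path, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(format = "csgan-checkpoint", version = 1L,
              class = class(model), config = model@config,
              params = model@params)
  saveRDS(obj, path)
  jsonlite::write_json(unclass(model@config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by \code{\link{saveCheckpoint}}.
#' @return the restored model object.
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "csgan-checkpoint") || obj$version != 1L)
    stop("unrecognized checkpoint format/version")
  new(obj$class, config = obj$config, params = obj$params)
}
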
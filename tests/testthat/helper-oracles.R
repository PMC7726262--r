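# Independent reference implementations used as oracles: a quadratic-cost
# centered DFT, a double-loop bilinear rotation, and a double-loop strided
# convolution. All deliberately naive and separate from the package's
# computational paths.

naiveCenteredDft <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(complex(real = 0), h, w)
  uu <- seq_len(h) - 1 - floor(h / 2)
  vv <- seq_len(w) - 1 - floor(w / 2)
  for (ui in seq_len(h)) for (vi in seq_len(w)) {
    s <- 0
    for (m in seq_len(h)) for (n in seq_len(w)) {
      ph <- -2 * pi * (uu[ui] * (m - 1) / h + vv[vi] * (n - 1) / w)
      s <- s + x[m, n] * complex(real = cos(ph), imaginary = sin(ph))
    }
    out[ui, vi] <- s / sqrt(h * w)
  }
  out
}

naiveCenteredIdftMag <- function(k) {
  h <- nrow(k); w <- ncol(k)
  out <- matrix(0, h, w)
  uu <- seq_len(h) - 1 - floor(h / 2)
  vv <- seq_len(w) - 1 - floor(w / 2)
  for (m in seq_len(h)) for (n in seq_len(w)) {
    s <- 0
    for (ui in seq_len(h)) for (vi in seq_len(w)) {
      ph <- 2 * pi * (uu[ui] * (m - 1) / h + vv[vi] * (n - 1) / w)
      s <- s + k[ui, vi] * complex(real = cos(ph), imaginary = sin(ph))
    }
    out[m, n] <- Mod(s / sqrt(h * w))
  }
  out
}

naiveRotate <- function(img, angleDeg) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angleDeg * pi / 180
  refl <- function(i, n) {
    p <- 2 * (n - 1)
    i <- (i - 1) %% p
    if (i < 0) i <- i + p
    if (i >= n) i <- p - i
    as.integer(i + 1)
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    sr <- cy + cos(th) * (r - cy) - sin(th) * (cc - cx)
    sc <- cx + sin(th) * (r - cy) + cos(th) * (cc - cx)
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    out[r, cc] <-
      (1 - fr) * (1 - fc) * img[refl(r0, h), refl(c0, w)] +
      (1 - fr) * fc * img[refl(r0, h), refl(c0 + 1, w)] +
      fr * (1 - fc) * img[refl(r0 + 1, h), refl(c0, w)] +
      fr * fc * img[refl(r0 + 1, h), refl(c0 + 1, w)]
  }
  out
}

# naive strided same-padded convolution matching the package's weight
# layout: W is (cout x k*k*cin), column index (kr, kc, cin), kr fastest
naiveConv <- function(x, W, b, k, stride, pad) {
  d <- dim(x)  # (H, W, C)
  H <- d[1]; Wd <- d[2]; C <- d[3]
  cout <- nrow(W)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
    acc <- b[co]
    for (ci in seq_len(C)) for (kc in seq_len(k)) for (kr in seq_len(k)) {
      ih <- (oh - 1) * stride - pad + kr
      iw <- (ow - 1) * stride - pad + kc
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= Wd) {
        wcol <- kr + k * (kc - 1) + k * k * (ci - 1)
        acc <- acc + W[co, wcol] * x[ih, iw, ci]
      }
    }
    y[oh, ow, co] <- acc
  }
  y
}

smallPhantom <- function(seed = 1L, size = 32L) {
  makePhantom(phantomSpec(height = size, width = size, nEllipses = 5L,
                          textureAmplitude = 0.1, seed = seed))
}
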
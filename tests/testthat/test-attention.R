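test_that("attention scores match a brute-force double loop", {
  set.seed(3)
  for (shape in list(c(2L, 2L, 16L), c(4L, 4L, 8L), c(8L, 8L, 8L))) {
    feat <- array(rnorm(prod(shape)), shape)
    ap <- initAttentionParams(shape[3], seed = shape[1])
    N <- shape[1] * shape[2]
    X <- t(matrix(feat, N, shape[3]))
    S <- attentionScores(feat, ap)
    ref <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N))
      ref[i, j] <- sum((ap$Wf %*% X[, i]) * (ap$Wg %*% X[, j]))
    expect_lt(max(abs(S - ref)), 1e-6)
  }
})

test_that("zero projections and single locations give the degenerate scores", {
  feat <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  ap <- initAttentionParams(8L, seed = 1L)
  ap0 <- ap; ap0$Wf[] <- 0; ap0$Wg[] <- 0
  expect_true(all(attentionScores(feat, ap0) == 0))
  f1 <- array(rnorm(8), c(1, 1, 8))
  s1 <- attentionScores(f1, ap)
  expect_equal(dim(s1), c(1L, 1L))
  expect_equal(s1[1, 1], sum((ap$Wf %*% as.vector(f1)) * (ap$Wg %*% as.vector(f1))))
})

test_that("the attention map is a stabilized query-major softmax", {
  set.seed(4)
  S <- matrix(rnorm(16), 4, 4)
  B <- attentionMap(S)
  expect_true(all(B >= 0))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-6)
  # direct high-precision evaluation: beta[j, i] = exp(s[i,j]) / sum_i
  ref <- t(apply(S, 2, function(col) exp(col) / sum(exp(col))))
  expect_lt(max(abs(B - ref)), 1e-9)
  # shift invariance per query slice
  expect_lt(max(abs(attentionMap(sweep(S, 2, c(5, -3, 100, 0), "+")) - B)), 1e-9)
  # uniform for zero scores
  expect_equal(attentionMap(matrix(0, 4, 4)), matrix(0.25, 4, 4))
  # stabilization: huge scores stay finite
  expect_true(all(is.finite(attentionMap(matrix(c(1e4, -1e4, 5e3, 0), 2)))))
})

test_that("attention output matches the loop evaluation of the projection", {
  set.seed(5)
  feat <- array(rnorm(2 * 4 * 8), c(2, 4, 8))
  ap <- initAttentionParams(8L, seed = 2L)
  B <- attentionMap(attentionScores(feat, ap))
  O <- attentionOutput(B, feat, ap)
  N <- 8
  X <- t(matrix(feat, N, 8))
  Om <- t(matrix(O, N, 8))
  for (j in seq_len(N)) {
    acc <- rep(0, 8)
    for (i in seq_len(N)) acc <- acc + B[j, i] * (ap$Wh %*% X[, i])
    expect_lt(max(abs(Om[, j] - ap$Wv %*% acc)), 1e-6)
  }
  # identity permutation map: o_j = Wv Wh x_j
  I <- diag(N)
  Oi <- attentionOutput(I, feat, ap)
  expect_lt(max(abs(t(matrix(Oi, N, 8)) - ap$Wv %*% ap$Wh %*% X)), 1e-9)
  # uniform map: every o_j is the projected spatial mean
  U <- matrix(1 / N, N, N)
  Ou <- attentionOutput(U, feat, ap)
  mu <- ap$Wv %*% ap$Wh %*% rowMeans(X)
  expect_lt(max(abs(t(matrix(Ou, N, 8)) - matrix(mu, 8, N))), 1e-9)
})

test_that("the full module is the identity at gamma = 0 and matches a scalar reference", {
  set.seed(6)
  feat <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  ap <- initAttentionParams(8L, seed = 3L)
  expect_identical(selfAttentionForward(feat, ap), feat)  # gamma = 0
  ap$gamma <- 0.7
  y <- selfAttentionForward(feat, ap)
  N <- 16
  X <- t(matrix(feat, N, 8))
  S <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N)
    S[i, j] <- sum((ap$Wf %*% X[, i]) * (ap$Wg %*% X[, j]))
  ref <- X
  for (j in 1:N) {
    bj <- exp(S[, j]) / sum(exp(S[, j]))
    acc <- rep(0, 8)
    for (i in 1:N) acc <- acc + bj[i] * (ap$Wh %*% X[, i])
    ref[, j] <- ap$gamma * (ap$Wv %*% acc) + X[, j]
  }
  expect_lt(max(abs(t(matrix(y, N, 8)) - ref)), 1e-5)
})

test_that("row normalization holds across many random inputs", {
  for (s in 1:50) {
    set.seed(s)
    feat <- array(rnorm(3 * 3 * 8, sd = 2), c(3, 3, 8))
    B <- attentionMap(attentionScores(feat, initAttentionParams(8L, seed = s)))
    expect_lt(max(abs(rowSums(B) - 1)), 1e-6)
  }
})

test_that("channel mismatch and divisibility are rejected", {
  expect_error(initAttentionParams(12L), "divisible by 8")
  feat <- array(rnorm(2 * 2 * 16), c(2, 2, 16))
  expect_error(attentionScores(feat, initAttentionParams(8L)), "mismatch")
})

test_that("attention heatmap rows export as PNG", {
  feat <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  B <- attentionMap(attentionScores(feat, initAttentionParams(8L, seed = 1L)))
  path <- file.path(tempdir(), "attn.png")
  writeAttentionHeatmap(B, 3L, 4L, 4L, path)
  expect_true(file.exists(path))
  expect_equal(dim(png::readPNG(path)), c(4L, 4L))
})
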
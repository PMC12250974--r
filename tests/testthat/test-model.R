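test_that("positional encoding matches its closed form", {
  pe <- positionalEncoding(8, 6)
  expect_equal(pe[1, ], c(0, 1, 0, 1, 0, 1))           # pos = 0 row
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-9)     # entry [1, 0], exponent 0
  expect_equal(pe, refPosEncoding(8, 6), tolerance = 1e-9)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positionalEncoding(8, 5), "even")
})

test_that("conv1d projection honours the shape contract and linearity", {
  x <- matrix(rnorm(32 * 1000), 32)
  W <- array(rnorm(40 * 32 * 3, 0, 0.1), c(40, 32, 3))
  out <- projectConv1d(x, W, numeric(40))
  expect_equal(dim(out), c(1000L, 40L))
  expect_equal(projectConv1d(matrix(0, 32, 1000), W, numeric(40)),
               matrix(0, 1000, 40))

  # kernel = 1 with identity-like weights copies channels into features
  Wid <- array(0, c(40, 32, 1))
  for (c in 1:32) Wid[c, c, 1] <- 1
  out2 <- projectConv1d(x, Wid, numeric(40))
  expect_equal(out2[, 1:32], t(x))
  expect_equal(out2[, 33:40], matrix(0, 1000, 8))

  # matches the loop oracle including zero-padded edges
  xs <- matrix(rnorm(3 * 10), 3)
  Ws <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
  bs <- rnorm(5)
  expect_equal(projectConv1d(xs, Ws, bs), refConv1d(xs, Ws, bs), tolerance = 1e-12)

  expect_error(projectConv1d(matrix(rnorm(6), 3), array(0, c(5, 3, 2)), numeric(5)),
               "invalid config")
  expect_error(projectConv1d(matrix(rnorm(6), 3, 2), array(0, c(5, 3, 5)), numeric(5)),
               "invalid config")
})

randWeights <- function(D, seed = 1) {
  set.seed(seed)
  g <- function() matrix(rnorm(D * D, 0, 0.3), D, D)
  list(Wq = g(), Wk = g(), Wv = g(), Wo = g(),
       bq = rnorm(D, 0, 0.1), bk = rnorm(D, 0, 0.1),
       bv = rnorm(D, 0, 0.1), bo = rnorm(D, 0, 0.1))
}

test_that("multi-head self-attention matches the brute-force oracle", {
  set.seed(7)
  O <- matrix(rnorm(5 * 8), 5, 8)
  w <- randWeights(8)
  got <- multiHeadSelfAttention(O, w, 2)
  ref <- refAttention(O, w, 2)
  expect_equal(got$out, ref$out, tolerance = 1e-6)
  expect_equal(got$attn, ref$attn, tolerance = 1e-6)

  # attention weights are row-stochastic
  for (h in 1:2) expect_equal(rowSums(got$attn[, , h]), rep(1, 5), tolerance = 1e-6)

  # single token: softmax over one element is 1, output = Wo-projected V
  O1 <- matrix(rnorm(8), 1, 8)
  got1 <- multiHeadSelfAttention(O1, w, 2)
  V1 <- O1 %*% w$Wv + w$bv
  expect_equal(got1$out, (V1 %*% w$Wo) + matrix(w$bo, 1), tolerance = 1e-9)
  expect_equal(as.vector(got1$attn), rep(1, 2))

  expect_error(multiHeadSelfAttention(matrix(0, 4, 9), w, 2), "divisible")
})

test_that("transformer block follows the written form: LN around attn + FFN(attn)", {
  set.seed(8)
  D <- 8
  O <- matrix(rnorm(6 * D), 6, D)
  w <- randWeights(D, 2)
  w$W1 <- matrix(rnorm(D * 16, 0, 0.3), D, 16); w$b1 <- rnorm(16, 0, 0.1)
  w$W2 <- matrix(rnorm(16 * D, 0, 0.3), 16, D); w$b2 <- rnorm(D, 0, 0.1)
  w$ln1g <- runif(D, 0.5, 1.5); w$ln1b <- rnorm(D, 0, 0.1)
  w$ln2g <- runif(D, 0.5, 1.5); w$ln2b <- rnorm(D, 0, 0.1)

  got <- cpp_transformer_block(O, w, 2, FALSE)
  expect_equal(got, refBlock(O, w, 2, FALSE), tolerance = 1e-8)
  expect_equal(dim(got), dim(O))

  # conventional two-residual form differs and matches its own oracle
  gotStd <- cpp_transformer_block(O, w, 2, TRUE)
  expect_equal(gotStd, refBlock(O, w, 2, TRUE), tolerance = 1e-8)
  expect_gt(max(abs(gotStd - got)), 1e-3)

  # with the FFN zeroed and identity affine the block is LN(attention output)
  w0 <- w
  w0$W1[] <- 0; w0$W2[] <- 0; w0$b1[] <- 0; w0$b2[] <- 0
  w0$ln2g[] <- 1; w0$ln2b[] <- 0
  attnOut <- refAttention(O, w0, 2)$out
  expect_equal(cpp_transformer_block(O, w0, 2, FALSE),
               refLayerNorm(attnOut, rep(1, D), rep(0, D)), tolerance = 1e-8)
})

test_that("layer norm rows are standardised before the affine map", {
  set.seed(9)
  X <- matrix(rnorm(40, 2, 3), 5, 8)
  ln <- cpp_layer_norm(X, runif(8), rnorm(8))
  expect_lt(max(abs(rowMeans(ln$xhat))), 1e-6)
  rowVar <- apply(ln$xhat, 1, function(r) mean((r - mean(r))^2))
  expect_lt(max(abs(rowVar - 1)), 1e-4)
})

test_that("gelu matches the exact Gaussian-CDF form", {
  x <- matrix(seq(-4, 4, length.out = 101), 1)
  expect_equal(cpp_gelu(x), refGelu(x), tolerance = 1e-6)
})

test_that("fusion trunk: shapes, determinism and weight sharing across modalities", {
  cfg <- modelConfig()
  p <- initializeModel(cfg, 4, 32, seed = 5)
  cl <- neurofuse:::cfgAsList(cfg)
  B <- 3
  Z <- matrix(rnorm(B * 32 * cfg@D), B * 32, cfg@D)
  f <- cpp_trunk_forward(p, cl, Z, B, FALSE)
  # pool stride 2 fixes the flattened length: ch * (L/2) * (D/2)
  expect_equal(dim(f), c(B, cfg@trunkChannels * 16L * (cfg@D %/% 2L)))
  expect_identical(cpp_trunk_forward(p, cl, Z, B, FALSE), f)

  # the same parameter set serves both modality branches: perturbing one
  # trunk weight changes the fused output of both
  d <- randomSampleSet(C = 4, L = 32, n = 4, seed = 6)
  m <- fitModel(d, cfg, trainConfig(epochs = 0L, seed = 1))
  fp0 <- forwardPass(m, d)
  m@params$trunk_convW[1, 1, 1] <- m@params$trunk_convW[1, 1, 1] + 0.5
  fp1 <- forwardPass(m, d)
  expect_gt(max(abs(fp1$fusedEeg - fp0$fusedEeg)), 0)
  expect_gt(max(abs(fp1$fusedEmg - fp0$fusedEmg)), 0)

  expect_error(cpp_trunk_forward(p, cl, matrix(rnorm(cfg@D), 1, cfg@D), 1, FALSE),
               "too short")
})

test_that("classifier heads are two-layer softmax maps with the stated contracts", {
  set.seed(10)
  f <- matrix(rnorm(6 * 12), 6, 12)
  p <- list(mod_W1 = matrix(rnorm(12 * 5, 0, 0.4), 12, 5), mod_b1 = rnorm(5),
            mod_W2 = matrix(rnorm(5 * 2, 0, 0.4), 5, 2), mod_b2 = rnorm(2))
  pr <- cpp_modal_head(p, f)
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-6)

  # zero weights -> uniform output
  p0 <- list(mod_W1 = matrix(0, 12, 5), mod_b1 = numeric(5),
             mod_W2 = matrix(0, 5, 2), mod_b2 = numeric(2))
  expect_equal(cpp_modal_head(p0, f), matrix(0.5, 6, 2))

  # softmax closed form for logits (2, 0): bias-only construction
  p2 <- list(mod_W1 = matrix(0, 12, 5), mod_b1 = numeric(5),
             mod_W2 = matrix(0, 5, 2), mod_b2 = c(2, 0))
  expect_equal(cpp_modal_head(p2, f)[1, ], c(0.8808, 0.1192), tolerance = 1e-4)

  # workload head consumes (eeg, emg) in fixed order: swapping inputs changes it
  d <- randomSampleSet(C = 4, L = 16, n = 4, seed = 11)
  m <- fitModel(d, modelConfig(), trainConfig(epochs = 0L, seed = 2))
  swapped <- pairedSampleSet(emgData(d), eegData(d), labels3(d),
                             windowIndex = windowIndices(d))
  expect_gt(max(abs(forwardPass(m, d)$probs - forwardPass(m, swapped)$probs)), 1e-6)
})

test_that("full forward pass reproduces the loop-based reference on a micro-batch", {
  cfg <- modelConfig(D = 8, nHeads = 2, nLayers = 2, ffnHidden = 16,
                     trunkChannels = 3, fcHidden = 10)
  C <- 5; L <- 16; B <- 4
  p <- initializeModel(cfg, C, L, seed = 12)
  set.seed(13)
  eeg <- array(rnorm(C * L * B), c(C, L, B))
  emg <- array(rnorm(C * L * B), c(C, L, B))
  got <- neurofuse:::cpp_forward(p, neurofuse:::cfgAsList(cfg), eeg, emg, TRUE)
  ref <- refForward(p, cfg, eeg, emg)
  expect_equal(got$probs, ref$probs, tolerance = 1e-5)
  expect_equal(got$fusedEeg, ref$fusedEeg, tolerance = 1e-5)
  expect_equal(got$fusedEmg, ref$fusedEmg, tolerance = 1e-5)
  expect_equal(got$modalProbsEeg, ref$modalProbsEeg, tolerance = 1e-5)
  expect_true(all(is.finite(got$probs)))
})

test_that("forward pass is finite and attention is counted per layer", {
  d <- randomSampleSet(C = 6, L = 16, n = 6, seed = 14)
  m <- fitModel(d, modelConfig(), trainConfig(epochs = 1L, seed = 3))
  fp <- forwardPass(m, d)
  expect_true(all(is.finite(fp$probs)))
  expect_true(all(is.finite(fp$fusedEeg)))
  # nLayers blocks x 2 branches per forward chunk
  expect_equal(fp$attnCalls, 2L * modelConfig()@nLayers)
})

test_that("gradient reversal is the identity in the forward pass", {
  x <- matrix(rnorm(20), 4)
  expect_identical(gradientReversal(x, 1.7), x)
  expect_error(gradientReversal(x, -1), "lambda")
})

test_that("model description propagates shapes", {
  df <- describeModel(modelConfig(), nChannels = 32L, windowLength = 1000L)
  expect_true(any(grepl("500", df$shape)))  # pool halves the 1000-sample axis
  expect_true(any(grepl("training only", df$stage)))
})
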
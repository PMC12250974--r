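# finite-difference verification of the hand-derived backward pass.
# With gradient reversal the parameter updates follow the surrogate field
# grad(L_cls) - lambda * grad(L_adv) upstream of the reversal and
# grad(L_cls + L_adv) for the classifier heads, so the check differentiates
# both loss components separately.

fdCheck <- function(cfg, nPerTensor = 2, eps = 1e-5, seed = 21) {
  C <- 5; L <- 12; B <- 4
  p <- initializeModel(cfg, C, L, seed = seed)
  d <- randomSampleSet(C = C, L = L, n = B, seed = seed + 1)
  g <- lossAndGrads(p, d, cfg)$grads
  lossParts <- function(pp) {
    r <- lossAndGrads(pp, d, cfg, wantGrads = FALSE)
    c(r$lossCls, r$lossAdv)
  }
  heads <- c("cls_W1", "cls_b1", "cls_W2", "cls_b2",
             "mod_W1", "mod_b1", "mod_W2", "mod_b2")
  worst <- 0
  set.seed(seed + 2)
  for (nm in setdiff(names(g), c("trunk_bn_rm", "trunk_bn_rv"))) {
    for (i in sample(length(g[[nm]]), min(nPerTensor, length(g[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps; lp <- lossParts(pp)
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] - eps; lm <- lossParts(pp)
      fd <- (lp - lm) / (2 * eps)
      expected <- if (nm %in% heads) fd[1] + fd[2] else fd[1] - cfg@grlLambda * fd[2]
      err <- abs(expected - g[[nm]][i]) / max(1e-6, abs(expected), abs(g[[nm]][i]))
      worst <- max(worst, err)
    }
  }
  worst
}

test_that("backpropagation matches finite differences through every layer", {
  cfg <- modelConfig(D = 8, nHeads = 2, nLayers = 2, ffnHidden = 16,
                     trunkChannels = 3, fcHidden = 10, grlLambda = 1.3)
  # tolerance absorbs the erf/exp approximations in the GELU hot path,
  # whose analytic derivative differs from the approximated function's
  # true derivative by ~1e-6 in absolute terms
  expect_lt(fdCheck(cfg), 2e-3)
})

test_that("backpropagation is also correct for ablation variants", {
  expect_lt(fdCheck(ablationConfig("no_adversary",
    modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10))), 5e-3)
  expect_lt(fdCheck(ablationConfig("no_transformer",
    modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10))), 5e-3)
  expect_lt(fdCheck(ablationConfig("eeg_only",
    modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10))), 5e-3)
  expect_lt(fdCheck(modelConfig(D = 8, nHeads = 2, trunkChannels = 3,
                                fcHidden = 10, standardBlock = TRUE)), 5e-3)
})

test_that("the trunk gradient is linear in the reversal scale lambda", {
  C <- 4; L <- 12; B <- 4
  d <- randomSampleSet(C = C, L = L, n = B, seed = 31)
  gradsAt <- function(lam) {
    cfg <- modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10,
                       grlLambda = lam)
    lossAndGrads(initializeModel(cfg, C, L, seed = 32), d, cfg)$grads
  }
  g0 <- gradsAt(0); g1 <- gradsAt(1); g2 <- gradsAt(2)
  for (nm in c("trunk_convW", "e_convW", "m_l1_Wq", "cnx1_W")) {
    delta1 <- g1[[nm]] - g0[[nm]]
    delta2 <- g2[[nm]] - g0[[nm]]
    expect_equal(delta2, 2 * delta1, tolerance = 1e-8)
  }
})

test_that("with lambda = 0 the trunk receives no gradient from the modal loss", {
  C <- 4; L <- 12; B <- 4
  d <- randomSampleSet(C = C, L = L, n = B, seed = 41)
  base <- modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10)
  cfgLam0 <- base; cfgLam0@grlLambda <- 0
  cfgNoAdv <- ablationConfig("no_adversary", base)
  pLam0 <- initializeModel(cfgLam0, C, L, seed = 42)
  pNoAdv <- initializeModel(cfgNoAdv, C, L, seed = 42)
  # identical shared weights by construction (same seed, modal head extra)
  gLam0 <- lossAndGrads(pLam0, d, cfgLam0)$grads
  gNoAdv <- lossAndGrads(pNoAdv, d, cfgNoAdv)$grads
  for (nm in names(gNoAdv)) {
    if (nm %in% c("trunk_bn_rm", "trunk_bn_rv")) next
    expect_equal(gLam0[[nm]], gNoAdv[[nm]], tolerance = 1e-10)
  }
  # the modal head itself still learns
  expect_gt(max(abs(gLam0$mod_W2)), 0)
})

test_that("gradient-reversal backward contract holds at the modal head", {
  set.seed(51)
  p <- list(mod_W1 = matrix(rnorm(12 * 6, 0, 0.4), 12, 6), mod_b1 = rnorm(6, 0, 0.1),
            mod_W2 = matrix(rnorm(6 * 2, 0, 0.4), 6, 2), mod_b2 = rnorm(2, 0, 0.1))
  f <- matrix(rnorm(5 * 12), 5, 12)
  targets <- c(0L, 1L, 0L, 1L, 0L)
  lambda <- 1.7
  gRev <- cpp_modal_head_input_grad(p, f, targets, lambda)
  # finite differences of the (unreversed) loss at 5 random coordinates
  eps <- 1e-6
  set.seed(52)
  for (k in 1:5) {
    i <- sample(nrow(f), 1); j <- sample(ncol(f), 1)
    fp <- f; fp[i, j] <- fp[i, j] + eps
    fm <- f; fm[i, j] <- fm[i, j] - eps
    fd <- (cpp_modal_head_loss(p, fp, targets) -
           cpp_modal_head_loss(p, fm, targets)) / (2 * eps)
    expect_equal(gRev[i, j], -lambda * fd, tolerance = 1e-4)
  }
  # lambda = 0 blocks all gradient flow into the trunk
  expect_equal(cpp_modal_head_input_grad(p, f, targets, 0), matrix(0, 5, 12))
})

test_that("loss decomposition and epoch bookkeeping are exact", {
  cfg <- modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10)
  d <- randomSampleSet(C = 4, L = 12, n = 8, seed = 61)
  r <- lossAndGrads(initializeModel(cfg, 4, 12, seed = 62), d, cfg)
  expect_equal(r$lossTotal, r$lossCls + r$lossAdv, tolerance = 1e-6)
  expect_equal(r$lossTotal, totalLoss(r$lossCls, r$lossAdv), tolerance = 1e-12)

  tr <- trainEpoch(initializeModel(cfg, 4, 12, seed = 62), list(), d, cfg,
                   trainConfig(seed = 1), order = 1:8)
  expect_equal(tr$lossTotal, tr$lossCls + tr$lossAdv, tolerance = 1e-6)
})

test_that("lr = 0 leaves parameters bit-exact; clipping bounds every element", {
  cfg <- modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10)
  d <- randomSampleSet(C = 4, L = 12, n = 8, seed = 71)
  p <- initializeModel(cfg, 4, 12, seed = 72)
  r0 <- trainEpoch(p, list(), d, cfg, trainConfig(lr = 0, seed = 1), order = 1:8)
  for (nm in setdiff(names(p), c("trunk_bn_rm", "trunk_bn_rv"))) {
    expect_identical(as.vector(r0$params[[nm]]), as.vector(p[[nm]]))
  }
  # clip bound applies to every gradient element, every step
  r1 <- trainEpoch(p, list(), d, cfg, trainConfig(clipAbs = 10, seed = 1), order = 1:8)
  expect_lte(r1$maxAbsGradPostClip, 10)
  r2 <- trainEpoch(p, list(), d, cfg, trainConfig(clipAbs = 1e-3, seed = 1), order = 1:8)
  expect_lte(r2$maxAbsGradPostClip, 1e-3)
})

test_that("training is exactly reproducible under a fixed seed", {
  cfg <- modelConfig(D = 8, nHeads = 2, trunkChannels = 3, fcHidden = 10)
  d <- randomSampleSet(C = 4, L = 12, n = 12, seed = 81)
  m1 <- fitModel(d, cfg, trainConfig(epochs = 3L, seed = 9))
  m2 <- fitModel(d, cfg, trainConfig(epochs = 3L, seed = 9))
  expect_identical(m1@history, m2@history)
  for (nm in names(m1@params)) expect_identical(m1@params[[nm]], m2@params[[nm]])
})
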
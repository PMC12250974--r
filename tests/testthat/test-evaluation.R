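test_that("decision rule takes the argmax with lowest-index tie-breaking", {
  expect_equal(decideLabels(matrix(c(0.1, 0.7, 0.2), 1)), 1L)
  expect_equal(decideLabels(matrix(c(0.4, 0.4, 0.2), 1)), 0L)
  p <- matrix(c(0.2, 0.5, 0.3,
                0.6, 0.1, 0.3), 2, byrow = TRUE)
  expect_equal(decideLabels(p), c(1L, 0L))
  # invariant under strictly increasing transforms
  expect_equal(decideLabels(exp(3 * p)), decideLabels(p))
})

test_that("accuracy is trace over total and permutation-invariant", {
  expect_equal(accuracyFromConfusion(diag(c(10, 10, 10))), 1.0)
  cm <- matrix(c(8, 1, 1,
                 2, 7, 1,
                 0, 2, 8), 3, byrow = TRUE)
  expect_equal(accuracyFromConfusion(cm), 23 / 30)
  perm <- c(3, 1, 2)
  expect_equal(accuracyFromConfusion(cm[perm, perm]), 23 / 30)
  expect_error(accuracyFromConfusion(matrix(0, 3, 3)), "undefined metric")
})

test_that("macro F1 equals the per-class tally oracle", {
  expect_equal(macroF1(diag(c(5, 6, 7))), 1.0)
  cm <- matrix(c(8, 1, 1,
                 2, 7, 1,
                 0, 2, 8), 3, byrow = TRUE)
  # reconstruct label vectors and tally independently
  truth <- rep(0:2, times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(i) rep(0:2, times = cm[i, ])))
  ref <- refTallyMetrics(truth, pred)
  expect_equal(macroF1(cm), ref$macroF1, tolerance = 1e-12)
  expect_equal(accuracyFromConfusion(cm), ref$acc, tolerance = 1e-12)
  expect_warning(f <- macroF1(matrix(c(5, 0, 5, 0, 0, 0, 3, 0, 3), 3)), "absent")
  expect_gte(f, 0); expect_lte(f, 1)
})

test_that("metrics agree with the tally oracle on random prediction vectors", {
  set.seed(141)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    cm <- confusionMatrix(truth, pred)
    ref <- refTallyMetrics(truth, pred)
    expect_equal(accuracyFromConfusion(cm), ref$acc, tolerance = 1e-12)
    f1 <- tryCatch(macroF1(cm), warning = function(w) suppressWarnings(macroF1(cm)))
    expect_equal(f1, ref$macroF1, tolerance = 1e-12)
  }
})

test_that("fold assignment is a stratified partition without window leakage", {
  d <- simulateDataset(simConfig(rateHz = 64, windowsPerClass = 10,
                                 nChannels = 4, seed = 5))
  fold <- neurofuse:::foldAssignment(d, 5L, seed = 7)
  # partition: every sample in exactly one fold
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), nSamples(d))
  # n divisible by 5: test fraction exactly 0.2
  expect_true(all(table(fold) == nSamples(d) / 5))
  # the two phase-paired samples of one window share a fold (leakage guard)
  key <- paste(subjectIds(d), windowIndices(d))
  expect_true(all(tapply(fold, key, function(f) length(unique(f))) == 1L))
  # stratification: every class present in every fold
  expect_true(all(table(labels3(d), fold) > 0))
  # reproducible under the seed
  expect_identical(fold, neurofuse:::foldAssignment(d, 5L, seed = 7))
})

test_that("cross-validation aggregates per-fold metrics consistently", {
  d <- simulateDataset(simConfig(rateHz = 64, windowsPerClass = 5,
                                 nChannels = 4, seed = 6))
  r <- fiveFoldCV(d, modelConfig(), trainConfig(epochs = 1L, seed = 8),
                  seed = 8, augment = augmentConfig(enabled = FALSE))
  expect_s4_class(r, "EvalReport")
  expect_length(r@perFold, 5L)
  accs <- vapply(r@perFold, `[[`, 1.0, "acc")
  f1s <- vapply(r@perFold, `[[`, 1.0, "f1")
  expect_equal(r@meanAcc, mean(accs), tolerance = 1e-10)
  expect_equal(r@sdAcc, sd(accs), tolerance = 1e-10)
  expect_equal(r@meanF1, mean(f1s), tolerance = 1e-10)
  expect_equal(r@sdF1, sd(f1s), tolerance = 1e-10)
  # confusion totals match the fold sizes and sum to the dataset
  expect_equal(sum(vapply(r@perFold, function(f) sum(f$confusion), 1.0)),
               nSamples(d))
  expect_error(fiveFoldCV(randomSampleSet(n = 4), nFolds = 5L),
               "insufficient data")
})

test_that("ablation variants have the stated structure", {
  d <- randomSampleSet(C = 4, L = 16, n = 10, seed = 151)
  # no_adversary: no modal-classifier parameters at all
  mNoAdv <- fitModel(d, ablationConfig("no_adversary"), trainConfig(epochs = 0L))
  expect_false(any(grepl("^mod_", names(mNoAdv@params))))
  # full model has them
  mFull <- fitModel(d, ablationConfig("full"), trainConfig(epochs = 0L))
  expect_true(all(c("mod_W1", "mod_W2") %in% names(mFull@params)))
  # no_transformer: attention is never invoked
  mNoTrf <- fitModel(d, ablationConfig("no_transformer"), trainConfig(epochs = 0L))
  expect_equal(forwardPass(mNoTrf, d)$attnCalls, 0L)
  expect_false(any(grepl("_l1_", names(mNoTrf@params))))
  # unimodal variants consume a single branch
  mEeg <- fitModel(d, ablationConfig("eeg_only"), trainConfig(epochs = 0L))
  expect_false(any(grepl("^m_", names(mEeg@params))))
  expect_equal(ncol(mEeg@params$cls_W1), modelConfig()@fcHidden)
  expect_error(ablationConfig("bogus"), "unknown ablation")
})

test_that("report serialisation mirrors the object", {
  d <- simulateDataset(simConfig(rateHz = 64, windowsPerClass = 5,
                                 nChannels = 4, seed = 9))
  r <- fiveFoldCV(d, modelConfig(), trainConfig(epochs = 1L, seed = 9),
                  seed = 9, augment = augmentConfig(enabled = FALSE))
  l <- reportAsList(r)
  expect_equal(l$mean_acc, r@meanAcc)
  expect_length(l$folds, 5L)
})
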
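test_that("the generator produces balanced labels and reproducible recordings", {
  cfg <- simConfig(rateHz = 64, windowsPerClass = 20, nChannels = 4, seed = 2)
  r <- simulateRecording(cfg)
  expect_length(r$labels, 60L)
  expect_equal(as.vector(table(r$labels)), rep(20L, 3))
  expect_equal(r$eeg@rateHz, 128)
  expect_equal(ncol(r$eeg@data), 60 * 128)
  expect_equal(ncol(r$emg@data), 60 * 64)

  r2 <- simulateRecording(cfg)
  expect_identical(r$eeg@data, r2$eeg@data)
  expect_identical(r$emg@data, r2$emg@data)

  expect_error(simConfig(rateHz = 64, classBandsHz = rbind(c(4, 8), c(8, 13), c(13, 40))),
               "within")
})

test_that("at high SNR the dominant spectral peak falls inside the class band", {
  cfg <- simConfig(rateHz = 64, windowsPerClass = 20, nChannels = 4,
                   snrDb = 60, seed = 3, shiftOffset = 0, shiftScale = 1,
                   shiftExtraAmp = 0)
  d <- simulateDataset(cfg)
  L <- dim(eegData(d))[2]
  freqs <- seq_len(L %/% 2) * 64 / L
  hits <- 0
  for (i in seq_len(nSamples(d))) {
    pw <- rowMeans((abs(stats::mvfft(t(eegData(d)[, , i])))^2)[2:(L %/% 2 + 1), , drop = FALSE])
    fpk <- freqs[which.max(pw)]
    band <- cfg@classBandsHz[labels3(d)[i] + 1, ]
    # periodogram resolution at 1 s windows is 1 Hz
    if (fpk >= band[1] - 1 && fpk <= band[2] + 1) hits <- hits + 1
  }
  expect_gte(hits / nSamples(d), 0.95)
})

test_that("the synthetic task is solvable by a no-learning band-power oracle", {
  cfg <- simConfig(rateHz = 64, windowsPerClass = 20, nChannels = 8,
                   snrDb = 20, seed = 4)
  d <- simulateDataset(cfg)
  expect_gt(bandPowerOracle(d, cfg@classBandsHz, cfg@rateHz), 0.9)
})

test_that("the modality shift does not alter labels or class structure", {
  base <- simConfig(rateHz = 64, windowsPerClass = 10, nChannels = 4, seed = 5)
  noShift <- simConfig(rateHz = 64, windowsPerClass = 10, nChannels = 4, seed = 5,
                       shiftOffset = 0, shiftScale = 1, shiftExtraAmp = 0)
  dS <- simulateDataset(base)
  d0 <- simulateDataset(noShift)
  expect_identical(labels3(dS), labels3(d0))
  # the EEG-like modality is untouched by the shift
  expect_identical(eegData(dS), eegData(d0))
  expect_gt(max(abs(emgData(dS) - emgData(d0))), 1)
})

test_that("shift probe detects a strong shift and sits at chance without one", {
  set.seed(6)
  n <- 80; p <- 30
  base <- matrix(rnorm(n * p), n, p)
  shifted <- base + 5  # 5-SD offset: linearly separable by construction
  feats <- rbind(base, shifted)
  mods <- rep(c("EEG", "EMG"), each = n)
  expect_gt(shiftProbe(feats, mods, seed = 1), 0.95)

  # identical generators: accuracy stays within the chance band over resamples
  acc <- vapply(1:10, function(s) {
    f <- rbind(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p), n, p))
    shiftProbe(f, mods, seed = s)
  }, 1.0)
  expect_gte(mean(acc), 0.4)
  expect_lte(mean(acc), 0.6)

  # invariant to a common affine transform applied to BOTH modalities
  expect_equal(shiftProbe(feats, mods, seed = 2),
               shiftProbe(feats * 3.7 - 2, mods, seed = 2))
  expect_error(shiftProbe(feats[1:10, ], mods[1:10]), "insufficient data")
})

test_that("the generated set flows through the real preprocessing path", {
  cfg <- simConfig(rateHz = 64, windowsPerClass = 6, nChannels = 4, seed = 7,
                   nSubjects = 2L)
  d <- simulateDataset(cfg)
  expect_equal(nSamples(d), 2L * 2L * 18L)  # subjects x phases x windows
  expect_setequal(unique(phases(d)), c("odd", "even"))
  expect_length(unique(subjectIds(d)), 2L)
  expect_equal(dim(eegData(d))[1:2], c(4L, 64L))
})
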
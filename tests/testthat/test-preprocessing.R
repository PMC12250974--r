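test_that("band-pass filter preserves shape, passes the band and rejects out-of-band", {
  # linearity: all-zero input stays zero
  z <- Recording(matrix(0, 32, 2000), 2000, "EEG")
  expect_equal(bandpassFilter(z, 0.1, 30)@data, matrix(0, 32, 2000))

  # 200 Hz sine is far outside the 0.1-30 Hz band: near-total rejection
  t10 <- seq(0, 10, by = 1 / 1000)[-1]
  s200 <- Recording(matrix(sin(2 * pi * 200 * t10), 1), 1000, "EEG")
  out <- bandpassFilter(s200, 0.1, 30)@data
  expect_lt(sqrt(mean(out^2)), 0.01 * sqrt(mean(s200@data^2)))

  # 10 Hz sine is in-band: RMS preserved within 5% (edges trimmed)
  s10 <- Recording(matrix(sin(2 * pi * 10 * t10), 1), 1000, "EEG")
  out10 <- bandpassFilter(s10, 0.1, 30)@data[1, 2001:8000]
  expect_equal(sqrt(mean(out10^2)), sqrt(0.5), tolerance = 0.05)

  # analytic magnitude-response oracle of the designed filter (the
  # forward-backward pass squares the single-pass magnitude)
  bf <- signal::butter(2, c(0.1, 30) / 500, type = "pass")
  expect_lt(refFilterGain(bf, 200, 1000), 0.01 * refFilterGain(bf, 10, 1000))
  expect_gt(20 * log10(refFilterGain(bf, 10, 1000) / refFilterGain(bf, 200, 1000)), 40)

  # in-band idempotence: filtering twice changes an in-band tone < 5% RMS
  once <- bandpassFilter(s10, 0.1, 30)
  twice <- bandpassFilter(once, 0.1, 30)
  mid <- 2001:8000
  expect_equal(sqrt(mean(twice@data[1, mid]^2)), sqrt(mean(once@data[1, mid]^2)),
               tolerance = 0.05)

  # band validation and Nyquist clipping
  expect_error(bandpassFilter(s10, 30, 10), "invalid band")
  expect_error(bandpassFilter(s10, 600, 700), "invalid band")
  emg <- Recording(matrix(rnorm(2 * 3000), 2), 1000, "EMG")
  expect_warning(filtered <- bandpassFilter(emg, 75, 500), "clipped to 450")
  expect_equal(dim(filtered@data), c(2L, 3000L))
})

test_that("windowing is an exact partition with the trailing remainder dropped", {
  rec <- Recording(matrix(rnorm(2 * 10700), 2), 1000, "EEG")
  w <- splitWindows(rec, 1)
  expect_length(w, 10L)
  expect_true(all(vapply(w, ncol, 1L) == 1000L))
  # concatenating the windows reproduces the truncated recording exactly
  expect_identical(do.call(cbind, w), rec@data[, 1:10000])

  expect_length(splitWindows(Recording(matrix(rnorm(2 * 999), 2), 1000, "EEG"), 1), 0L)
  w2 <- splitWindows(Recording(matrix(rnorm(32 * 2000), 32), 2000, "EEG"), 1)
  expect_length(w2, 1L)
  expect_equal(dim(w2[[1]]), c(32L, 2000L))
})

test_that("interleaved downsampling splits odd/even points and re-interleaves exactly", {
  s <- interleaveDownsample(matrix(1:6, 1))
  expect_equal(s$odd[1, ], c(1, 3, 5))
  expect_equal(s$even[1, ], c(2, 4, 6))

  x <- matrix(rnorm(32 * 2000), 32)
  st <- interleaveDownsample(x)
  expect_equal(dim(st$odd), c(32L, 1000L))
  expect_equal(dim(st$even), c(32L, 1000L))
  expect_identical(reInterleave(st$odd, st$even), x)  # bit-exact identity

  expect_error(interleaveDownsample(matrix(1:5, 1)), "even")
})

test_that("pairing doubles the window count and preserves labels", {
  eegw <- matrix(rnorm(32 * 2000), 32)
  emgw <- matrix(rnorm(32 * 1000), 32)
  ps <- pairSamples(interleaveDownsample(eegw), emgw, 2L, "S1", 7L)
  expect_equal(nSamples(ps), 2L)
  expect_equal(labels3(ps), c(2L, 2L))
  expect_equal(phases(ps), c("odd", "even"))
  expect_identical(emgData(ps)[, , 1], emgData(ps)[, , 2])  # same EMG window
  expect_identical(eegData(ps)[, , 1], eegw[, seq(1, 2000, 2)])

  expect_error(pairSamples(interleaveDownsample(eegw), emgw[, 1:500], 0L),
               "pairing error")

  # full path: 2 x windows, one label per window, grouped by window index
  eeg <- Recording(matrix(rnorm(4 * 2000 * 60), 4), 2000, "EEG", "S9")
  emg <- Recording(matrix(rnorm(4 * 1000 * 60), 4), 1000, "EMG", "S9")
  d <- makePairedDataset(eeg, emg, rep(0:2, 20), filter = FALSE)
  expect_equal(nSamples(d), 120L)
  expect_equal(sum(table(windowIndices(d)) == 2L), 60L)
  expect_equal(as.vector(table(labels3(d))), c(40L, 40L, 40L))
  expect_error(makePairedDataset(eeg, Recording(matrix(rnorm(4 * 900), 4), 900, "EMG"),
                                 rep(0, 60)), "twice")
})

test_that("segment label table maps windows to labels", {
  seg <- data.frame(segment_start_s = c(0, 5), segment_end_s = c(3, 8),
                    label = c(0L, 2L))
  expect_equal(segmentLabels(seg, 8, 1), c(0L, 0L, 0L, NA, NA, 2L, 2L, 2L))
})
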
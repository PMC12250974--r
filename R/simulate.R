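#' @include AllClasses.R preprocessing.R
NULL

#' Construct a SimConfig
#'
#' @param nSubjects number of simulated subjects.
#' @param windowsPerClass 1-s windows generated per workload class.
#' @param nChannels channels per modality.
#' @param rateHz common sampling rate after pairing (the EEG-like stream is
#'   generated at twice this rate).
#' @param classBandsHz 3 x 2 matrix of (low, high) band pairs, one per class.
#' @param snrDb per-channel signal-to-noise ratio in dB.
#' @param shiftOffset additive offset applied to the EMG-like modality
#'   (in units of the unit-amplitude class signal).
#' @param shiftScale multiplicative scale applied to the EMG-like modality.
#' @param shiftExtraBandHz (low, high) band of the extra nuisance oscillation
#'   carried only by the EMG-like modality.
#' @param shiftExtraAmp amplitude of the nuisance oscillation (0 disables it).
#' @param seed base RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSubjects = 1L, windowsPerClass = 60L, nChannels = 32L,
                      rateHz = 1000, classBandsHz = rbind(c(4, 8), c(8, 13), c(13, 30)),
                      snrDb = 10, shiftOffset = 2, shiftScale = 1.5,
                      shiftExtraBandHz = c(1, 3), shiftExtraAmp = 1, seed = 1L) {
  new("SimConfig", nSubjects = as.integer(nSubjects),
      windowsPerClass = as.integer(windowsPerClass),
      nChannels = as.integer(nChannels), rateHz = rateHz,
      classBandsHz = classBandsHz, snrDb = snrDb, shiftOffset = shiftOffset,
      shiftScale = shiftScale, shiftExtraBandHz = shiftExtraBandHz,
      shiftExtraAmp = shiftExtraAmp, seed = as.integer(seed))
}

#' Simulate one subject's paired continuous recordings
#'
#' Generates an EEG-like recording at twice \code{rateHz} and an EMG-like
#' recording at \code{rateHz}, window-by-window. Every 1-s window carries a
#' unit-amplitude sinusoid whose frequency is drawn uniformly from the
#' window's class band (random phase per channel) plus white Gaussian noise
#' scaled to \code{snrDb}. Both modalities share the window's class frequency;
#' the EMG-like signal is additionally pushed through the inter-modality
#' distribution shift: multiplied by \code{shiftScale}, offset by
#' \code{shiftOffset}, and given an extra nuisance-band sinusoid. Labels are
#' one per window in shuffled class order.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param subject subject index (enters the RNG stream).
#' @return list with \code{eeg} (\linkS4class{Recording} at 2 x rateHz),
#'   \code{emg} (\linkS4class{Recording} at rateHz) and integer \code{labels},
#'   one per window.
#' @export
simulateRecording <- function(cfg, subject = 1L) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed * 10000L + as.integer(subject))
  nWin <- 3L * cfg@windowsPerClass
  labels <- sample(rep(0:2, cfg@windowsPerClass))
  nE <- as.integer(2 * cfg@rateHz)   # EEG-like window length
  nM <- as.integer(cfg@rateHz)       # EMG-like window length
  C <- cfg@nChannels
  noiseSd <- sqrt(0.5 / 10^(cfg@snrDb / 10))  # unit sinusoid has power 1/2
  tE <- (seq_len(nE) - 1) / (2 * cfg@rateHz)
  tM <- (seq_len(nM) - 1) / cfg@rateHz
  eeg <- matrix(0, C, nWin * nE)
  emg <- matrix(0, C, nWin * nM)
  for (w in seq_len(nWin)) {
    band <- cfg@classBandsHz[labels[w] + 1L, ]
    f <- stats::runif(1, band[1], band[2])
    phE <- stats::runif(C, 0, 2 * pi)
    phM <- stats::runif(C, 0, 2 * pi)
    sigE <- sin(outer(phE, 2 * pi * f * tE, `+`))
    sigM <- sin(outer(phM, 2 * pi * f * tM, `+`))
    winE <- sigE + matrix(stats::rnorm(C * nE, 0, noiseSd), C)
    winM <- sigM + matrix(stats::rnorm(C * nM, 0, noiseSd), C)
    # inter-modality distribution shift on the EMG-like stream
    winM <- cfg@shiftScale * winM + cfg@shiftOffset
    # nuisance-band draws are consumed regardless of amplitude so that
    # enabling/disabling the shift never alters the EEG-side RNG stream
    fn <- stats::runif(1, cfg@shiftExtraBandHz[1], cfg@shiftExtraBandHz[2])
    phN <- stats::runif(C, 0, 2 * pi)
    if (cfg@shiftExtraAmp > 0) {
      winM <- winM + cfg@shiftExtraAmp * sin(outer(phN, 2 * pi * fn * tM, `+`))
    }
    eeg[, ((w - 1L) * nE + 1L):(w * nE)] <- winE
    emg[, ((w - 1L) * nM + 1L):(w * nM)] <- winM
  }
  sid <- sprintf("sim%02d", as.integer(subject))
  list(eeg = Recording(eeg, 2 * cfg@rateHz, "EEG", sid),
       emg = Recording(emg, cfg@rateHz, "EMG", sid),
       labels = labels)
}

#' Simulate a paired-sample dataset
#'
#' Runs \code{\link{simulateRecording}} for every subject and pushes the
#' recordings through the real preprocessing path (windowing, interleaved
#' downsampling of the double-rate EEG-like stream, pairing), so the produced
#' \linkS4class{PairedSampleSet} has exactly the structure of preprocessed
#' real data: 2 x windows samples, phase tags, labels. Band-pass filtering is
#' off by default because the synthetic signal is band-limited by construction
#' and the high-pass would remove the offset component of the modality shift.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param filter apply the band-pass filters of the real pipeline.
#' @param ... passed to \code{\link{makePairedDataset}} when \code{filter}.
#' @return a \linkS4class{PairedSampleSet}.
#' @export
simulateDataset <- function(cfg, filter = FALSE, ...) {
  sets <- lapply(seq_len(cfg@nSubjects), function(s) {
    r <- simulateRecording(cfg, s)
    makePairedDataset(r$eeg, r$emg, r$labels, windowS = 1, filter = filter, ...)
  })
  bindSampleSets(sets)
}

#' Band-power oracle classification accuracy
#'
#' A no-learning baseline establishing that the synthetic task is solvable:
#' each window is assigned the class whose band holds the largest mean
#' periodogram power (averaged over channels) of its EEG stream.
#'
#' @param data a \linkS4class{PairedSampleSet}.
#' @param classBandsHz 3 x 2 band matrix used by the generator.
#' @param rateHz sampling rate of the paired windows.
#' @return classification accuracy in [0, 1].
#' @export
bandPowerOracle <- function(data, classBandsHz, rateHz) {
  n <- nSamples(data)
  L <- dim(data@eeg)[2]
  freqs <- (seq_len(L %/% 2)) * rateHz / L
  pred <- integer(n)
  for (i in seq_len(n)) {
    pw <- abs(stats::mvfft(t(data@eeg[, , i])))^2
    pw <- rowMeans(pw[2:(L %/% 2 + 1L), , drop = FALSE])
    bandPower <- vapply(seq_len(nrow(classBandsHz)), function(cl) {
      sel <- freqs >= classBandsHz[cl, 1] & freqs <= classBandsHz[cl, 2]
      mean(pw[sel])
    }, 1.0)
    pred[i] <- which.max(bandPower) - 1L
  }
  mean(pred == data@label)
}
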
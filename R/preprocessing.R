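#' @include AllClasses.R paired-samples.R
NULL

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel of a recording independently with a 4th-order
#' Butterworth band-pass (order-2 prototype), applied forward and backward
#' (\code{signal::filtfilt}) so the filter is zero-phase and window alignment
#' across modalities is preserved. The reference bands are 0.1-30 Hz for EEG
#' and 75-500 Hz for EMG; an upper edge at or above the Nyquist frequency is
#' unrealizable and is clipped to 0.45 x rate with a warning (relevant for the
#' 500 Hz EMG edge at a 1 kHz rate).
#'
#' @param rec a \linkS4class{Recording}.
#' @param lowHz lower band edge in Hz, > 0.
#' @param highHz upper band edge in Hz, > lowHz.
#' @return the filtered \linkS4class{Recording}, same shape.
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 4000), 2), 2000, "EEG")
#' filtered <- bandpassFilter(rec, 0.1, 30)
#' @export
bandpassFilter <- function(rec, lowHz, highHz) {
  stopifnot(is(rec, "Recording"))
  if (nrow(rec@data) == 0L || ncol(rec@data) == 0L) stop("empty recording")
  ny <- rec@rateHz / 2
  if (!(lowHz > 0 && highHz > lowHz)) stop("invalid band: need 0 < lowHz < highHz")
  if (lowHz >= ny) stop("invalid band: lower edge at or above Nyquist")
  if (highHz >= ny) {
    highHz <- 0.45 * rec@rateHz
    warning(sprintf("upper band edge at/above Nyquist; clipped to %g Hz", highHz))
    if (highHz <= lowHz) stop("invalid band after Nyquist clipping")
  }
  bf <- signal::butter(2, c(lowHz, highHz) / ny, type = "pass")
  out <- t(apply(rec@data, 1, function(ch) signal::filtfilt(bf, ch)))
  if (nrow(rec@data) == 1L) out <- matrix(out, nrow = 1L)
  Recording(out, rec@rateHz, rec@modality, rec@subjectId)
}

#' Split a recording into non-overlapping windows
#'
#' Consecutive windows of \code{windowS} seconds; a trailing remainder shorter
#' than one window is discarded.
#'
#' @param rec a \linkS4class{Recording}.
#' @param windowS window length in seconds.
#' @return a list of channels x samples matrices (possibly empty).
#' @export
splitWindows <- function(rec, windowS = 1) {
  stopifnot(is(rec, "Recording"), windowS > 0)
  w <- as.integer(round(windowS * rec@rateHz))
  n <- floor(ncol(rec@data) / w)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) rec@data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE])
}

#' Interleaved EEG downsampling
#'
#' Splits one EEG window sampled at twice the EMG rate into two streams of
#' half the length: the "odd" stream takes sample points 1, 3, 5, ... and the
#' "even" stream takes 2, 4, 6, .... Re-interleaving the two streams
#' reconstructs the input exactly.
#'
#' @param eegWindow channels x samples matrix with an even sample count.
#' @return list with elements \code{odd} and \code{even}.
#' @examples
#' interleaveDownsample(matrix(1:6, 1))
#' @export
interleaveDownsample <- function(eegWindow) {
  eegWindow <- as.matrix(eegWindow)
  n <- ncol(eegWindow)
  if (n %% 2L != 0L) stop("interleaved downsampling requires an even sample count")
  list(odd = eegWindow[, seq(1L, n, by = 2L), drop = FALSE],
       even = eegWindow[, seq(2L, n, by = 2L), drop = FALSE])
}

#' Re-interleave two downsampled streams
#'
#' Inverse of \code{\link{interleaveDownsample}}.
#'
#' @param odd,even channels x N matrices.
#' @return channels x 2N matrix.
#' @export
reInterleave <- function(odd, even) {
  stopifnot(identical(dim(odd), dim(even)))
  out <- matrix(0, nrow(odd), 2L * ncol(odd))
  out[, seq(1L, ncol(out), by = 2L)] <- odd
  out[, seq(2L, ncol(out), by = 2L)] <- even
  out
}

#' Pair downsampled EEG streams with an EMG window
#'
#' Each of the two interleaved EEG streams is paired with the same EMG window
#' and label, producing two paired samples per source window (the dataset size
#' doubles relative to the window count).
#'
#' @param eegStreams list with \code{odd} and \code{even} matrices.
#' @param emgWindow channels x samples matrix, same sample count as each stream.
#' @param label integer workload label in {0,1,2}.
#' @param subjectId subject token.
#' @param windowIndex index of the source window.
#' @return a \linkS4class{PairedSampleSet} of length 2.
#' @export
pairSamples <- function(eegStreams, emgWindow, label, subjectId = "S1",
                        windowIndex = 0L) {
  emgWindow <- as.matrix(emgWindow)
  if (ncol(eegStreams$odd) != ncol(emgWindow) ||
      ncol(eegStreams$even) != ncol(emgWindow)) {
    stop("pairing error: EEG stream and EMG window sample counts differ")
  }
  d <- c(nrow(eegStreams$odd), ncol(emgWindow))
  de <- c(nrow(emgWindow), ncol(emgWindow))
  eeg <- array(c(eegStreams$odd, eegStreams$even), c(d, 2L))
  emg <- array(c(emgWindow, emgWindow), c(de, 2L))
  pairedSampleSet(eeg, emg, label = c(label, label), subjectId = subjectId,
                  windowIndex = windowIndex, phase = c("odd", "even"))
}

#' Expand segment labels to per-window labels
#'
#' @param segments data.frame with columns \code{segment_start_s},
#'   \code{segment_end_s}, \code{label}.
#' @param nWindows number of windows.
#' @param windowS window length in seconds.
#' @return integer label per window (NA where no segment covers the window).
#' @export
segmentLabels <- function(segments, nWindows, windowS = 1) {
  mid <- (seq_len(nWindows) - 0.5) * windowS
  lab <- rep(NA_integer_, nWindows)
  for (i in seq_len(nrow(segments))) {
    sel <- mid >= segments$segment_start_s[i] & mid < segments$segment_end_s[i]
    lab[sel] <- as.integer(segments$label[i])
  }
  lab
}

#' Full preprocessing path: recordings to paired samples
#'
#' Runs the preprocessing chain on one subject's continuous recordings:
#' optional zero-phase band-pass of each modality (on the continuous signal,
#' before windowing, so edge transients hit only the recording ends),
#' non-overlapping 1-s windowing, interleaved downsampling of each EEG window
#' into two streams, and pairing of each stream with the matching EMG window.
#' The EEG recording must be sampled at twice the EMG rate.
#'
#' @param eegRec EEG \linkS4class{Recording} (rate = 2 x EMG rate).
#' @param emgRec EMG \linkS4class{Recording}.
#' @param labels integer label per window, or a segment data.frame
#'   (see \code{\link{segmentLabels}}).
#' @param windowS window length in seconds.
#' @param filter apply the band-pass filters first.
#' @param eegBand,emgBand band edges in Hz used when \code{filter} is TRUE.
#' @return a \linkS4class{PairedSampleSet} with 2 x (number of windows) samples.
#' @export
makePairedDataset <- function(eegRec, emgRec, labels, windowS = 1,
                              filter = TRUE, eegBand = c(0.1, 30),
                              emgBand = c(75, 500)) {
  stopifnot(is(eegRec, "Recording"), is(emgRec, "Recording"))
  if (abs(eegRec@rateHz - 2 * emgRec@rateHz) > 1e-9) {
    stop("EEG rate must be twice the EMG rate for interleaved pairing")
  }
  if (filter) {
    eegRec <- bandpassFilter(eegRec, eegBand[1], eegBand[2])
    emgRec <- suppressWarnings(bandpassFilter(emgRec, emgBand[1], emgBand[2]))
  }
  we <- splitWindows(eegRec, windowS)
  wm <- splitWindows(emgRec, windowS)
  n <- min(length(we), length(wm))
  if (n == 0L) stop("insufficient data: recording shorter than one window")
  if (is.data.frame(labels)) labels <- segmentLabels(labels, n, windowS)
  if (length(labels) < n) stop("need one label per window")
  keep <- which(!is.na(labels[seq_len(n)]))
  sets <- lapply(keep, function(i) {
    pairSamples(interleaveDownsample(we[[i]]), wm[[i]], labels[i],
                subjectId = eegRec@subjectId, windowIndex = i - 1L)
  })
  bindSampleSets(sets)
}
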
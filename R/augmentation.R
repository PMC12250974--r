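#' @include AllClasses.R paired-samples.R
NULL

#' Construct an AugmentConfig
#'
#' @param sigmaRel relative noise SD: the additive Gaussian noise SD equals
#'   \code{sigmaRel} times the per-channel SD of the training set.
#' @param sigma absolute noise SD in signal units; overrides \code{sigmaRel}
#'   when not NA.
#' @param flipAxis "time" (reverse sample order; default) or "channel".
#' @param flipProb NA for the deterministic copy-and-flip expansion; a value in
#'   (0,1] instead flips each copied sample with that probability.
#' @param enabled logical master switch.
#' @param seed RNG seed for the noise copies.
#' @return An \linkS4class{AugmentConfig}.
#' @export
augmentConfig <- function(sigmaRel = 0.05, sigma = NA_real_, flipAxis = "time",
                          flipProb = NA_real_, enabled = TRUE, seed = 1L) {
  new("AugmentConfig", sigmaRel = sigmaRel, sigma = sigma, flipAxis = flipAxis,
      flipProb = flipProb, enabled = enabled, seed = as.integer(seed))
}

#' Flip a signal window
#'
#' Reverses the window along the requested axis. Applying the flip twice is
#' the identity.
#'
#' @param x channels x samples matrix.
#' @param axis "time" or "channel".
#' @return the flipped matrix, same shape.
#' @examples
#' flipSample(matrix(1:3, 1))
#' @export
flipSample <- function(x, axis = "time") {
  x <- as.matrix(x)
  switch(axis,
         time = x[, rev(seq_len(ncol(x))), drop = FALSE],
         channel = x[rev(seq_len(nrow(x))), , drop = FALSE],
         stop("axis must be 'time' or 'channel'"))
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with SD \code{sigma} to every entry;
#' reproducible under a fixed seed.
#'
#' @param x numeric matrix or array.
#' @param sigma noise SD, >= 0.
#' @param seed optional RNG seed.
#' @return the noised object, same shape.
#' @export
addGaussianNoise <- function(x, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("invalid parameter: sigma must be a single number >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(x)
  x + array(stats::rnorm(length(x), 0, sigma), dim(x))
}

#' @describeIn augmentSet expand a training set to originals plus one flipped
#'   and one noised copy per sample (3x the size). Both modalities of a copy
#'   receive the same kind of transform; labels and metadata are preserved.
#'   Sets tagged as test data are refused.
setMethod("augmentSet", "PairedSampleSet", function(x, cfg = augmentConfig()) {
  if (!cfg@enabled) return(x)
  if (x@role == "test") stop("refusing to augment a test set")
  n <- nSamples(x)
  if (n == 0L) stop("cannot augment an empty sample set")
  set.seed(cfg@seed)

  flipArr <- function(a) {
    if (cfg@flipAxis == "time") a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
    else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  }
  flipped <- x
  if (is.na(cfg@flipProb) || cfg@flipProb >= 1) {
    flipped@eeg <- flipArr(x@eeg)
    flipped@emg <- flipArr(x@emg)
  } else {
    do <- stats::runif(n) < cfg@flipProb
    fe <- flipArr(x@eeg); fm <- flipArr(x@emg)
    flipped@eeg[, , do] <- fe[, , do]
    flipped@emg[, , do] <- fm[, , do]
  }

  # per-channel noise SD: relative to the training-set SD unless absolute
  chanSd <- function(a) apply(a, 1, stats::sd)
  sdE <- if (is.na(cfg@sigma)) cfg@sigmaRel * chanSd(x@eeg) else rep(cfg@sigma, dim(x@eeg)[1])
  sdM <- if (is.na(cfg@sigma)) cfg@sigmaRel * chanSd(x@emg) else rep(cfg@sigma, dim(x@emg)[1])
  noised <- x
  noised@eeg <- x@eeg + array(stats::rnorm(length(x@eeg)), dim(x@eeg)) * sdE
  noised@emg <- x@emg + array(stats::rnorm(length(x@emg)), dim(x@emg)) * sdM

  out <- bindSampleSets(list(x, flipped, noised), role = x@role)
  out@augmented <- TRUE
  out
})
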
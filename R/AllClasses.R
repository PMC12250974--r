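#' @import methods
NULL

#' Continuous multichannel recording
#'
#' A single continuous recording of one modality: a channels x samples matrix
#' together with its sampling rate. EEG and EMG recordings of the pipeline's
#' reference acquisition are 32 channels at 2 kHz and 1 kHz respectively, but
#' any positive rate is accepted.
#'
#' @slot modality either \code{"EEG"} or \code{"EMG"}.
#' @slot data numeric matrix, channels x samples; must be finite.
#' @slot rateHz sampling rate in Hz.
#' @slot subjectId subject identifier.
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    modality = "character",
    data = "matrix",
    rateHz = "numeric",
    subjectId = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- NULL
  if (!object@modality %in% c("EEG", "EMG")) {
    msg <- c(msg, "modality must be 'EEG' or 'EMG'")
  }
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) || object@rateHz <= 0) {
    msg <- c(msg, "rateHz must be a single positive number")
  }
  if (!all(is.finite(object@data))) {
    msg <- c(msg, "recording contains NaN/Inf values")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix.
#' @param rateHz sampling rate in Hz.
#' @param modality \code{"EEG"} or \code{"EMG"}.
#' @param subjectId subject identifier token.
#' @return A \linkS4class{Recording}.
#' @examples
#' rec <- Recording(matrix(rnorm(32 * 2000), 32), 2000, "EEG")
#' channelCount(rec)
#' @export
Recording <- function(data, rateHz, modality, subjectId = "S1") {
  new("Recording", modality = modality, data = as.matrix(data),
      rateHz = rateHz, subjectId = subjectId)
}

#' Set of paired EEG/EMG windows
#'
#' The basis samples of the pipeline: N paired 1-s windows, each holding one
#' EEG window and one EMG window of identical dimensions, a 3-level workload
#' label (0 = low, 1 = moderate, 2 = high), the subject, the index of the
#' source window within the recording, and the interleaved-downsampling phase
#' the EEG stream came from ("odd" = samples 1,3,5,..., "even" = 2,4,6,...).
#' Signal arrays are stored channels x samples x N.
#'
#' @slot eeg numeric array, channels x samples x N.
#' @slot emg numeric array, channels x samples x N.
#' @slot label integer vector in {0,1,2}.
#' @slot subjectId character vector of subject tokens.
#' @slot windowIndex integer vector, source window index.
#' @slot phase character vector, "odd" or "even".
#' @slot role provenance tag: "unsplit", "train" or "test".
#' @slot augmented logical flag: TRUE once augmentation copies were added.
#'
#' @exportClass PairedSampleSet
setClass("PairedSampleSet",
  representation(
    eeg = "array",
    emg = "array",
    label = "integer",
    subjectId = "character",
    windowIndex = "integer",
    phase = "character",
    role = "character",
    augmented = "logical"
  )
)

setValidity("PairedSampleSet", function(object) {
  msg <- NULL
  de <- dim(object@eeg); dm <- dim(object@emg)
  if (length(de) != 3L || length(dm) != 3L) {
    return("eeg and emg must be 3-d arrays (channels x samples x N)")
  }
  if (!identical(de[2:3], dm[2:3])) {
    msg <- c(msg, "eeg and emg must have identical sample counts and N")
  }
  n <- de[3]
  if (length(object@label) != n) msg <- c(msg, "label length must equal N")
  if (length(object@label) && !all(object@label %in% 0:2)) {
    msg <- c(msg, "labels must be integers in {0,1,2}")
  }
  if (length(object@subjectId) != n) msg <- c(msg, "subjectId length must equal N")
  if (length(object@windowIndex) != n) msg <- c(msg, "windowIndex length must equal N")
  if (length(object@phase) != n) msg <- c(msg, "phase length must equal N")
  if (length(object@phase) && !all(object@phase %in% c("odd", "even"))) {
    msg <- c(msg, "phase must be 'odd' or 'even'")
  }
  if (!object@role %in% c("unsplit", "train", "test")) {
    msg <- c(msg, "role must be 'unsplit', 'train' or 'test'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Model architecture configuration
#'
#' All architecture hyperparameters of the dual-branch network: the common
#' feature dimension D the Conv1D projections map both modalities to, kernel
#' sizes, attention heads and encoder depth, the shared fusion trunk
#' (one conv/batch-norm/ReLU block, a 2x2 max-pool, then ConvNeXt-style
#' depthwise-conv/LayerNorm/GELU blocks), classifier widths, and the
#' gradient-reversal scale lambda. Per-head query/key/value dimensions are
#' D / nHeads.
#'
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    D = "integer", kEeg = "integer", kEmg = "integer",
    nHeads = "integer", nLayers = "integer", ffnHidden = "integer",
    trunkChannels = "integer", nFusionBlocks = "integer",
    fcHidden = "integer", nClasses = "integer", nModalities = "integer",
    grlLambda = "numeric", standardBlock = "logical",
    useTransformer = "logical", useAdversary = "logical",
    modality = "character"
  ),
  prototype(
    D = 8L, kEeg = 3L, kEmg = 3L, nHeads = 4L, nLayers = 1L,
    ffnHidden = 32L, trunkChannels = 4L, nFusionBlocks = 3L,
    fcHidden = 32L, nClasses = 3L, nModalities = 2L,
    grlLambda = 1.0, standardBlock = FALSE,
    useTransformer = TRUE, useAdversary = TRUE, modality = "both"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- NULL
  if (object@D %% object@nHeads != 0L) msg <- c(msg, "D must be divisible by nHeads")
  if (object@D %% 2L != 0L) msg <- c(msg, "D must be even (sin/cos positional encoding)")
  if (object@kEeg %% 2L == 0L || object@kEmg %% 2L == 0L) {
    msg <- c(msg, "temporal kernel sizes must be odd (same-padding)")
  }
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@nModalities < 2L) msg <- c(msg, "nModalities must be >= 2")
  if (object@grlLambda < 0) msg <- c(msg, "grlLambda must be >= 0")
  if (!object@modality %in% c("both", "eeg", "emg")) {
    msg <- c(msg, "modality must be 'both', 'eeg' or 'emg'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Training configuration
#'
#' Optimisation settings for joint adversarial training: learning rate 1e-3
#' and element-wise gradient clipping at absolute value 10 (the published
#' recipe), Adam by default, with early stopping on a training-loss plateau.
#'
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    lr = "numeric", clipAbs = "numeric", epochs = "integer",
    batchSize = "integer", optimizer = "character", seed = "integer",
    patience = "integer", minDelta = "numeric", grlWarmup = "logical"
  ),
  prototype(
    lr = 1e-3, clipAbs = 10, epochs = 60L, batchSize = 32L,
    optimizer = "adam", seed = 1L, patience = 15L, minDelta = 1e-4,
    grlWarmup = TRUE
  )
)

setValidity("TrainConfig", function(object) {
  msg <- NULL
  if (object@lr < 0) msg <- c(msg, "lr must be >= 0")
  if (object@clipAbs <= 0) msg <- c(msg, "clipAbs must be > 0")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@optimizer %in% c("adam", "sgd")) msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (is.null(msg)) TRUE else msg
})

#' Augmentation configuration
#'
#' Training-set augmentation settings: the set is expanded to originals plus a
#' flipped copy and an additive-Gaussian-noise copy of every sample (3x).
#' The noise SD is relative by default: sigmaRel times the per-channel SD of
#' the training set, so that EEG (microvolt) and EMG (millivolt) channels are
#' perturbed proportionately; an absolute sigma can be given instead.
#'
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(
    sigmaRel = "numeric", sigma = "numeric", flipAxis = "character",
    flipProb = "numeric", enabled = "logical", seed = "integer"
  ),
  prototype(
    sigmaRel = 0.05, sigma = NA_real_, flipAxis = "time",
    flipProb = NA_real_, enabled = TRUE, seed = 1L
  )
)

setValidity("AugmentConfig", function(object) {
  msg <- NULL
  if (!is.na(object@sigma) && object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@sigmaRel < 0) msg <- c(msg, "sigmaRel must be >= 0")
  if (!object@flipAxis %in% c("time", "channel")) {
    msg <- c(msg, "flipAxis must be 'time' or 'channel'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Synthetic paired-signal generator configuration
#'
#' Study conditions for the synthetic benchmark: each workload class carries a
#' band-limited oscillation in its own frequency band (defaults 4-8, 8-13 and
#' 13-30 Hz, loosely evoking workload-dependent EEG rhythms) plus white noise
#' at \code{snrDb}. The EMG-like stream carries the same class signal pushed
#' through a controllable inter-modality distribution shift: an additive
#' offset, a multiplicative scale and an extra nuisance band. The EEG-like
#' stream is generated at twice \code{rateHz} so the interleaved-downsampling
#' path is exercised end to end.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSubjects = "integer", windowsPerClass = "integer", nChannels = "integer",
    rateHz = "numeric", classBandsHz = "matrix", snrDb = "numeric",
    shiftOffset = "numeric", shiftScale = "numeric",
    shiftExtraBandHz = "numeric", shiftExtraAmp = "numeric", seed = "integer"
  ),
  prototype(
    nSubjects = 1L, windowsPerClass = 60L, nChannels = 32L, rateHz = 1000,
    classBandsHz = rbind(c(4, 8), c(8, 13), c(13, 30)),
    snrDb = 10, shiftOffset = 2, shiftScale = 1.5,
    shiftExtraBandHz = c(1, 3), shiftExtraAmp = 1, seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  ny <- object@rateHz / 2
  if (any(object@classBandsHz <= 0) || any(object@classBandsHz >= ny)) {
    msg <- c(msg, "class bands must lie within (0, rateHz/2)")
  }
  if (nrow(object@classBandsHz) != 3L || ncol(object@classBandsHz) != 2L) {
    msg <- c(msg, "classBandsHz must be a 3 x 2 matrix of (low, high) pairs")
  }
  if (object@windowsPerClass < 5L) msg <- c(msg, "windowsPerClass must be >= 5")
  if (length(object@shiftExtraBandHz) != 2L ||
      any(object@shiftExtraBandHz <= 0) || any(object@shiftExtraBandHz >= ny)) {
    msg <- c(msg, "shiftExtraBandHz must be a (low, high) pair within (0, rateHz/2)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Trained model
#'
#' Parameters of the two feature-extraction branches, the shared fusion trunk
#' and the classifier heads, plus the per-epoch training history. The
#' retained parameter set is the best epoch by training loss.
#'
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(
    params = "list",
    modelConfig = "ModelConfig",
    trainConfig = "TrainConfig",
    history = "data.frame",
    bestEpoch = "integer",
    nChannels = "integer",
    windowLength = "integer",
    variant = "character"
  )
)

#' Cross-validation evaluation report
#'
#' Per-fold accuracy, macro F1, confusion matrix and modality-probe accuracy,
#' with mean and SD summaries over the folds.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    perFold = "list",
    meanAcc = "numeric", sdAcc = "numeric",
    meanF1 = "numeric", sdF1 = "numeric",
    variant = "character", nFolds = "integer"
  )
)

setValidity("EvalReport", function(object) {
  if (length(object@perFold) != object@nFolds) {
    "perFold must hold exactly nFolds entries"
  } else TRUE
})
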
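#' @include AllClasses.R model.R
NULL

#' Linear modality probe
#'
#' Quantifies the residual inter-modality distribution shift in a feature
#' space: a held-out ridge-regularised logistic probe is trained to tell
#' EEG-derived from EMG-derived feature vectors. Probe accuracy near 1
#' indicates a strong shift; accuracy near 0.5 (chance) indicates aligned,
#' modality-invariant features. The probe is invariant to any common affine
#' transform applied to both modalities, since such a transform leaves the
#' class separation between the two groups unchanged.
#'
#' @param features numeric matrix, one feature vector per row.
#' @param modality character/factor of "EEG"/"EMG" per row.
#' @param trainFrac fraction used to fit the probe; the rest measures accuracy.
#' @param seed RNG seed for the stratified split.
#' @param lambda ridge penalty of the logistic probe.
#' @return held-out probe accuracy in [0, 1].
#' @export
shiftProbe <- function(features, modality, trainFrac = 0.7, seed = 1L,
                       lambda = 0.05) {
  features <- as.matrix(features)
  modality <- as.character(modality)
  n <- nrow(features)
  if (n < 20L) stop("insufficient data: need at least 20 feature vectors")
  if (length(modality) != n) stop("one modality tag per feature row required")
  set.seed(seed)
  trainIdx <- logical(n)
  for (m in unique(modality)) {
    idx <- which(modality == m)
    trainIdx[sample(idx, round(trainFrac * length(idx)))] <- TRUE
  }
  y <- as.integer(modality == "EMG")
  # constant columns carry no information and break standardisation
  keep <- apply(features[trainIdx, , drop = FALSE], 2, stats::sd) > 0
  if (!any(keep)) return(0.5)
  fit <- glmnet::glmnet(features[trainIdx, keep, drop = FALSE],
                        factor(y[trainIdx], levels = 0:1),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  pred <- stats::predict(fit, features[!trainIdx, keep, drop = FALSE],
                         type = "class")
  mean(as.integer(pred) == y[!trainIdx])
}

#' Modality-probe accuracy of a trained model
#'
#' Trains the variant on a stratified split of the data, computes fused
#' features of the held-out windows through the shared trunk, and probes them
#' for modality identity with \code{\link{shiftProbe}}. This is the package's
#' operational measure of how much inter-modality shift survives fusion.
#'
#' @param data a \linkS4class{PairedSampleSet}.
#' @param modelCfg a \linkS4class{ModelConfig} with \code{modality = "both"}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param holdoutFrac fraction of windows held out for probing.
#' @param seed RNG seed (split, training, probe).
#' @param augment a \linkS4class{AugmentConfig} for the training part.
#' @return list with \code{probeAcc}, \code{testAcc} (workload accuracy on the
#'   held-out windows) and the fitted \code{model}.
#' @export
modalityProbe <- function(data, modelCfg = modelConfig(),
                          trainCfg = trainConfig(), holdoutFrac = 0.2,
                          seed = 1L, augment = augmentConfig()) {
  stopifnot(modelCfg@modality == "both")
  nParts <- max(2L, as.integer(round(1 / holdoutFrac)))  # 0.2 -> 5 parts
  fold <- foldAssignment(data, nParts, seed)
  test <- setSampleRole(data[fold == 1L], "test")
  train <- setSampleRole(data[fold != 1L], "train")
  if (augment@enabled) {
    acfg <- augment
    acfg@seed <- as.integer(seed * 1000L + 1L)
    train <- augmentSet(train, acfg)
  }
  tcfg <- trainCfg
  tcfg@seed <- as.integer(seed)
  model <- fitModel(train, modelCfg, tcfg)
  # probe the representation the adversary acts on: trunk batch-norm in
  # batch-statistics mode, exactly as the modal classifier saw it
  fp <- forwardPass(model, test, training = TRUE)
  probeAcc <- shiftProbe(rbind(fp$fusedEeg, fp$fusedEmg),
                         rep(c("EEG", "EMG"), each = nSamples(test)),
                         seed = seed)
  pred <- predictLabels(model, test)
  list(probeAcc = probeAcc, testAcc = mean(pred == test@label), model = model)
}
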
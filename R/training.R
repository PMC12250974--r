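#' @include AllClasses.R model.R
NULL

#' Construct a TrainConfig
#'
#' @param lr learning rate (published recipe: 1e-3).
#' @param clipAbs element-wise gradient-clipping bound (published recipe: 10).
#' @param epochs maximum training epochs.
#' @param batchSize mini-batch size.
#' @param optimizer "adam" (default) or "sgd".
#' @param seed seed governing initialisation and shuffling.
#' @param patience early-stopping patience on the training-loss plateau.
#' @param minDelta minimum loss improvement that resets the patience counter.
#' @param grlWarmup ramp the gradient-reversal scale from 0 to its configured
#'   value over training (2/(1+exp(-10 p)) - 1 with p the epoch fraction, the
#'   standard domain-adversarial schedule); stabilises the early minimax game.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lr = 1e-3, clipAbs = 10, epochs = 60L, batchSize = 32L,
                        optimizer = "adam", seed = 1L, patience = 15L,
                        minDelta = 1e-4, grlWarmup = TRUE) {
  new("TrainConfig", lr = lr, clipAbs = clipAbs, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), optimizer = optimizer,
      seed = as.integer(seed), patience = as.integer(patience),
      minDelta = minDelta, grlWarmup = grlWarmup)
}

#' Cross-entropy of a probability vector
#'
#' Returns -log p(true class); the probability is floored at 1e-12 for
#' numerical safety.
#'
#' @param probs probability vector (sums to 1).
#' @param trueLabel 0-based class index.
#' @return a nonnegative number.
#' @examples
#' crossEntropy(c(0.5, 0.25, 0.25), 1)  # log(4)
#' @export
crossEntropy <- function(probs, trueLabel) {
  if (trueLabel < 0 || trueLabel >= length(probs)) stop("invalid label: out of range")
  -log(max(probs[trueLabel + 1L], 1e-12))
}

#' Total training loss
#'
#' The joint objective is the plain sum of the workload classification loss
#' and the adversarial modal loss; the min-max between the modal classifier
#' and the fusion trunk is realised solely through gradient reversal, so a
#' single minimisation of the sum suffices.
#'
#' @param lCls classification loss.
#' @param lAdv adversarial loss.
#' @return their sum.
#' @export
totalLoss <- function(lCls, lAdv) {
  stopifnot(is.finite(lCls), is.finite(lAdv))
  lCls + lAdv
}

# internal: training tensors from a sample set for the configured modality
trainingTensors <- function(data, cfg) {
  list(eeg = if (cfg@modality != "emg") data@eeg else emptyCube(),
       emg = if (cfg@modality != "eeg") data@emg else emptyCube(),
       labels = data@label)
}

#' One training epoch
#'
#' Runs one pass over the shuffled data in mini-batches: forward through both
#' branches, classification loss on the concatenated fused features and
#' adversarial loss on each modality's (gradient-reversed) fused feature,
#' backpropagation, element-wise gradient clipping to [-clipAbs, clipAbs],
#' then an optimizer step.
#'
#' @param params model parameter list.
#' @param optState optimizer state (empty list on the first call).
#' @param data a \linkS4class{PairedSampleSet} (training data).
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param order integer permutation of samples for this epoch (defaults to a
#'   fresh shuffle from the session RNG).
#' @return list with updated \code{params}, \code{optState} and the epoch's
#'   mean \code{lossTotal}, \code{lossCls}, \code{lossAdv}, \code{modalAcc},
#'   \code{workloadAcc} and \code{maxAbsGradPostClip}.
#' @export
trainEpoch <- function(params, optState, data, modelCfg, trainCfg,
                       order = sample.int(nSamples(data)), lambdaScale = 1) {
  cl <- cfgAsList(modelCfg)
  cl$grlLambda <- cl$grlLambda * lambdaScale
  tt <- trainingTensors(data, modelCfg)
  cpp_train_epoch(params, optState, cl, tt$eeg, tt$emg,
                  tt$labels, order, trainCfg@lr, trainCfg@clipAbs,
                  trainCfg@batchSize, trainCfg@optimizer)
}

#' Fit the model
#'
#' End-to-end joint training by minimising classification + adversarial loss.
#' Initialisation, shuffling and all other randomness derive from
#' \code{trainCfg@seed}, so identical seeds give identical trajectories.
#' The best epoch by training classification loss is retained as the model
#' checkpoint and drives early stopping (the adversarial term is excluded
#' from the monitor because the reversal-scale warm-up makes it
#' non-comparable across epochs); training stops early after
#' \code{patience} epochs without improvement.
#'
#' @param data a \linkS4class{PairedSampleSet} of (augmented) training samples.
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param variant label stored with the model (see \code{\link{runAblation}}).
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{TrainedModel}.
#' @export
fitModel <- function(data, modelCfg = modelConfig(), trainCfg = trainConfig(),
                     variant = "full", verbose = FALSE) {
  stopifnot(is(data, "PairedSampleSet"))
  if (data@role == "test") stop("refusing to train on a test set")
  nC <- channelCount(data)
  L <- dim(data@eeg)[2]
  set.seed(trainCfg@seed)
  params <- initializeModel(modelCfg, nC, L, seed = trainCfg@seed)
  optState <- list()
  hist <- vector("list", trainCfg@epochs)
  best <- params; bestLoss <- Inf; bestEpoch <- 0L; wait <- 0L
  for (ep in seq_len(trainCfg@epochs)) {
    lam <- if (trainCfg@grlWarmup && trainCfg@epochs > 1) {
      p <- (ep - 1) / (trainCfg@epochs - 1)
      2 / (1 + exp(-10 * p)) - 1
    } else 1
    r <- trainEpoch(params, optState, data, modelCfg, trainCfg, lambdaScale = lam)
    params <- r$params; optState <- r$optState
    hist[[ep]] <- data.frame(epoch = ep, lossTotal = r$lossTotal,
                             lossCls = r$lossCls, lossAdv = r$lossAdv,
                             modalAcc = r$modalAcc, workloadAcc = r$workloadAcc,
                             maxAbsGradPostClip = r$maxAbsGradPostClip)
    if (verbose) {
      message(sprintf("epoch %3d: loss %.4f (cls %.4f adv %.4f) acc %.3f modal %.3f",
                      ep, r$lossTotal, r$lossCls, r$lossAdv, r$workloadAcc,
                      ifelse(is.na(r$modalAcc), NA, r$modalAcc)))
    }
    if (r$lossCls < bestLoss - trainCfg@minDelta) {
      bestLoss <- r$lossCls; best <- params; bestEpoch <- ep; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= trainCfg@patience) break
    }
  }
  history <- if (any(!vapply(hist, is.null, TRUE))) {
    do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  } else {
    data.frame(epoch = integer(), lossTotal = numeric(), lossCls = numeric(),
               lossAdv = numeric(), modalAcc = numeric(),
               workloadAcc = numeric(), maxAbsGradPostClip = numeric())
  }
  new("TrainedModel", params = if (bestEpoch > 0L) best else params,
      modelConfig = modelCfg, trainConfig = trainCfg, history = history,
      bestEpoch = bestEpoch, nChannels = as.integer(nC),
      windowLength = as.integer(L), variant = variant)
}

#' Loss and gradients of one batch (diagnostic)
#'
#' Exposes the joint loss decomposition and the raw (pre-clipping) parameter
#' gradients of a single batch; used for gradient checking and for verifying
#' the gradient-reversal contract.
#'
#' @param params parameter list.
#' @param data a \linkS4class{PairedSampleSet}.
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param wantGrads return gradients (FALSE: loss only).
#' @return list with \code{lossTotal}, \code{lossCls}, \code{lossAdv},
#'   \code{modalAcc}, \code{workloadAcc} and optionally \code{grads}.
#' @export
lossAndGrads <- function(params, data, modelCfg, wantGrads = TRUE) {
  tt <- trainingTensors(data, modelCfg)
  cpp_loss_grads(params, cfgAsList(modelCfg), tt$eeg, tt$emg, tt$labels,
                 TRUE, wantGrads)
}

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel (%s): %d channels x %d samples, %d epochs trained (best %d)\n",
              object@variant, object@nChannels, object@windowLength,
              nrow(object@history), object@bestEpoch))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final loss %.4f (cls %.4f, adv %.4f), train acc %.3f\n",
                last$lossTotal, last$lossCls, last$lossAdv, last$workloadAcc))
  }
})
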
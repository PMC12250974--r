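#' @include AllClasses.R training.R
NULL

#' Confusion matrix
#'
#' @param trueLabels,predLabels integer vectors of 0-based class labels.
#' @param nClasses number of classes.
#' @return an nClasses x nClasses integer matrix, rows = true, cols = predicted.
#' @export
confusionMatrix <- function(trueLabels, predLabels, nClasses = 3L) {
  stopifnot(length(trueLabels) == length(predLabels))
  cm <- matrix(0L, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1L), pred = 0:(nClasses - 1L)))
  for (i in seq_along(trueLabels)) {
    cm[trueLabels[i] + 1L, predLabels[i] + 1L] <- cm[trueLabels[i] + 1L, predLabels[i] + 1L] + 1L
  }
  cm
}

#' Multi-class accuracy
#'
#' Fraction of correctly classified samples: the trace of the confusion matrix
#' over its total (the multi-class generalisation of (TP+TN)/(TP+TN+FP+FN)).
#'
#' @param cm confusion matrix (rows = true, cols = predicted).
#' @return accuracy in [0, 1].
#' @export
accuracyFromConfusion <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("undefined metric: empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Macro-averaged F1 score
#'
#' Per class, one-vs-rest F1 = 2 * precision * recall / (precision + recall);
#' the macro score is their unweighted mean. A class with no true and no
#' predicted instances contributes F1 = 0 with a warning.
#'
#' @param cm confusion matrix (rows = true, cols = predicted).
#' @return macro F1 in [0, 1].
#' @export
macroF1 <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("undefined metric: empty confusion matrix")
  n <- nrow(cm)
  f1 <- numeric(n)
  for (c in seq_len(n)) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    if (tp + fp + fn == 0) {
      warning(sprintf("class %d absent from truth and predictions; F1 set to 0", c - 1L))
      f1[c] <- 0
    } else if (tp == 0) {
      f1[c] <- 0
    } else {
      prec <- tp / (tp + fp)
      rec <- tp / (tp + fn)
      f1[c] <- 2 * prec * rec / (prec + rec)
    }
  }
  mean(f1)
}

#' Decision rule: class with maximal predicted probability
#'
#' Ties are broken toward the lowest class index. The rule is invariant under
#' any strictly increasing transform of the probabilities.
#'
#' @param probs N x nClasses matrix of class probabilities (or scores).
#' @return integer vector of 0-based labels.
#' @export
decideLabels <- function(probs) {
  as.integer(apply(as.matrix(probs), 1, which.max) - 1L)
}

#' @describeIn predictLabels argmax of the workload-classifier probabilities
#'   (ties broken toward the lowest class index); the modal classifier plays
#'   no part at inference.
setMethod("predictLabels", "TrainedModel", function(model, data, ...) {
  decideLabels(forwardPass(model, data, ...)$probs)
})

# stratified assignment of window keys to folds; the two interleaving phases
# of one source window share a key and always land in the same fold
foldAssignment <- function(data, nFolds, seed) {
  key <- paste(data@subjectId, data@windowIndex, sep = "::")
  uk <- unique(key)
  keyLabel <- data@label[match(uk, key)]
  set.seed(seed)
  foldOfKey <- integer(length(uk))
  for (cl in unique(keyLabel)) {
    idx <- which(keyLabel == cl)
    idx <- idx[sample.int(length(idx))]
    foldOfKey[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  foldOfKey[match(key, uk)]
}

#' Stratified five-fold cross-validation
#'
#' Splits one subject's paired samples into \code{nFolds} near-equal parts
#' (the published 8:2 protocol for five folds), stratified by class. The two
#' phase-paired samples derived from one EEG window always land in the same
#' part, so no test window leaks into training. Augmentation is applied after
#' splitting, to the training part only. Each part serves as the test set
#' once; per-fold accuracy, macro F1, confusion matrix and a post-hoc linear
#' modality-probe accuracy on the test-fold fused features are aggregated as
#' mean and SD.
#'
#' @param data a \linkS4class{PairedSampleSet}.
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param nFolds number of folds.
#' @param seed seed for the fold assignment and per-fold training seeds.
#' @param augment a \linkS4class{AugmentConfig} applied to training folds.
#' @param probeModality also estimate the modality-probe accuracy per fold
#'   (only meaningful for two-modality variants).
#' @param variant label stored in the report.
#' @return an \linkS4class{EvalReport}.
#' @export
fiveFoldCV <- function(data, modelCfg = modelConfig(), trainCfg = trainConfig(),
                       nFolds = 5L, seed = 1L, augment = augmentConfig(),
                       probeModality = FALSE, variant = "full") {
  if (length(unique(data@windowIndex)) < nFolds) {
    stop("insufficient data: need at least as many windows as folds")
  }
  fold <- foldAssignment(data, nFolds, seed)
  perFold <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    train <- setSampleRole(data[fold != f], "train")
    test <- setSampleRole(data[fold == f], "test")
    if (augment@enabled) {
      acfg <- augment
      acfg@seed <- as.integer(seed * 1000L + f)
      train <- augmentSet(train, acfg)
    }
    tcfg <- trainCfg
    tcfg@seed <- as.integer(seed * 100L + f)
    model <- fitModel(train, modelCfg, tcfg, variant = variant)
    pred <- predictLabels(model, test)
    cm <- confusionMatrix(test@label, pred, modelCfg@nClasses)
    probeAcc <- NA_real_
    if (probeModality && modelCfg@modality == "both") {
      fp <- forwardPass(model, test, training = TRUE)
      probeAcc <- shiftProbe(rbind(fp$fusedEeg, fp$fusedEmg),
                             rep(c("EEG", "EMG"), each = nSamples(test)),
                             seed = tcfg@seed)
    }
    perFold[[f]] <- list(acc = accuracyFromConfusion(cm), f1 = macroF1(cm),
                         confusion = cm, modalAcc = probeAcc,
                         nTest = nSamples(test))
  }
  accs <- vapply(perFold, `[[`, 1.0, "acc")
  f1s <- vapply(perFold, `[[`, 1.0, "f1")
  new("EvalReport", perFold = perFold,
      meanAcc = mean(accs), sdAcc = stats::sd(accs),
      meanF1 = mean(f1s), sdF1 = stats::sd(f1s),
      variant = variant, nFolds = as.integer(nFolds))
}

#' Ablation harness
#'
#' Re-runs cross-validation with components removed:
#' \describe{
#'   \item{full}{the complete model (transformer branches + adversarial
#'     alignment).}
#'   \item{no_adversary}{no modal classifier / gradient reversal; plain
#'     concatenation fusion of the two transformer branches.}
#'   \item{no_transformer}{Conv1D features feed the fusion trunk directly
#'     (no positional encoding, no attention); adversarial alignment kept.}
#'   \item{eeg_only, emg_only}{single-branch unimodal models, no modal
#'     classifier, workload classifier on one fused vector.}
#' }
#'
#' @param variant one of the names above.
#' @param data a \linkS4class{PairedSampleSet}.
#' @param modelCfg base \linkS4class{ModelConfig} (variant flags are derived).
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param ... passed to \code{\link{fiveFoldCV}}.
#' @return an \linkS4class{EvalReport}.
#' @export
runAblation <- function(variant, data, modelCfg = modelConfig(),
                        trainCfg = trainConfig(), ...) {
  cfg <- ablationConfig(variant, modelCfg)
  fiveFoldCV(data, cfg, trainCfg, variant = variant, ...)
}

#' Derive the model configuration of an ablation variant
#'
#' @param variant ablation name (see \code{\link{runAblation}}).
#' @param modelCfg base configuration.
#' @return the modified \linkS4class{ModelConfig}.
#' @export
ablationConfig <- function(variant, modelCfg = modelConfig()) {
  cfg <- modelCfg
  switch(variant,
    full = {
      cfg@useTransformer <- TRUE; cfg@useAdversary <- TRUE; cfg@modality <- "both"
    },
    no_adversary = {
      cfg@useTransformer <- TRUE; cfg@useAdversary <- FALSE; cfg@modality <- "both"
    },
    no_transformer = {
      cfg@useTransformer <- FALSE; cfg@useAdversary <- TRUE; cfg@modality <- "both"
    },
    eeg_only = {
      cfg@useTransformer <- TRUE; cfg@useAdversary <- FALSE; cfg@modality <- "eeg"
    },
    emg_only = {
      cfg@useTransformer <- TRUE; cfg@useAdversary <- FALSE; cfg@modality <- "emg"
    },
    stop(sprintf("unknown ablation variant '%s'", variant))
  )
  cfg
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s, %d folds):\n", object@variant, object@nFolds))
  cat(sprintf("  accuracy %.4f +/- %.4f | macro F1 %.4f +/- %.4f\n",
              object@meanAcc, object@sdAcc, object@meanF1, object@sdF1))
  pa <- vapply(object@perFold, `[[`, 1.0, "modalAcc")
  if (any(!is.na(pa))) {
    cat(sprintf("  modality-probe accuracy %.4f +/- %.4f\n",
                mean(pa, na.rm = TRUE), stats::sd(pa, na.rm = TRUE)))
  }
})

#' Serialise an EvalReport to plain lists (for JSON/CSV export)
#'
#' @param report an \linkS4class{EvalReport}.
#' @return a list mirroring the report.
#' @export
reportAsList <- function(report) {
  list(variant = report@variant,
       folds = lapply(report@perFold, function(f) {
         list(acc = f$acc, f1 = f$f1, modal_acc = f$modalAcc, n_test = f$nTest,
              confusion = unname(apply(f$confusion, 1, as.integer, simplify = FALSE)))
       }),
       mean_acc = report@meanAcc, sd_acc = report@sdAcc,
       mean_f1 = report@meanF1, sd_f1 = report@sdF1)
}
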
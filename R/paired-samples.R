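#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PairedSampleSet
#'
#' @param eeg channels x samples x N array (or channels x samples matrix for N = 1).
#' @param emg array of the same shape.
#' @param label integer labels in {0,1,2}, length N.
#' @param subjectId subject tokens (recycled if length 1).
#' @param windowIndex source window indices (recycled if length 1).
#' @param phase interleaving phase, "odd" or "even" (recycled if length 1).
#' @param role provenance tag.
#' @return A \linkS4class{PairedSampleSet}.
#' @export
pairedSampleSet <- function(eeg, emg, label, subjectId = "S1",
                            windowIndex = 0L, phase = "odd",
                            role = "unsplit") {
  if (length(dim(eeg)) == 2L) eeg <- array(eeg, c(dim(eeg), 1L))
  if (length(dim(emg)) == 2L) emg <- array(emg, c(dim(emg), 1L))
  n <- dim(eeg)[3]
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  new("PairedSampleSet", eeg = eeg, emg = emg, label = as.integer(rec(label)),
      subjectId = rec(as.character(subjectId)),
      windowIndex = as.integer(rec(windowIndex)), phase = rec(phase),
      role = role, augmented = FALSE)
}

#' @rdname nSamples
setMethod("nSamples", "PairedSampleSet", function(x) dim(x@eeg)[3])

#' @rdname nSamples
setMethod("nSamples", "Recording", function(x) ncol(x@data))

#' @rdname nSamples
setMethod("channelCount", "Recording", function(x) nrow(x@data))

#' @rdname nSamples
setMethod("channelCount", "PairedSampleSet", function(x) dim(x@eeg)[1])

#' @rdname eegData
setMethod("eegData", "PairedSampleSet", function(x) x@eeg)

#' @rdname eegData
setMethod("emgData", "PairedSampleSet", function(x) x@emg)

#' @rdname eegData
setMethod("labels3", "PairedSampleSet", function(x) x@label)

#' @rdname eegData
setMethod("subjectIds", "PairedSampleSet", function(x) x@subjectId)

#' @rdname eegData
setMethod("windowIndices", "PairedSampleSet", function(x) x@windowIndex)

#' @rdname eegData
setMethod("phases", "PairedSampleSet", function(x) x@phase)

#' @rdname eegData
setMethod("sampleRole", "PairedSampleSet", function(x) x@role)

#' Subset a PairedSampleSet
#'
#' @param x a \linkS4class{PairedSampleSet}.
#' @param i integer or logical index over samples.
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "PairedSampleSet", function(x, i, j, ..., drop = FALSE) {
  new("PairedSampleSet",
      eeg = x@eeg[, , i, drop = FALSE], emg = x@emg[, , i, drop = FALSE],
      label = x@label[i], subjectId = x@subjectId[i],
      windowIndex = x@windowIndex[i], phase = x@phase[i],
      role = x@role, augmented = x@augmented)
})

#' Concatenate paired sample sets
#'
#' @param sets a list of \linkS4class{PairedSampleSet} objects with matching
#'   channel counts and window lengths.
#' @param role provenance tag of the result (default: keep the first set's).
#' @return one combined \linkS4class{PairedSampleSet}.
#' @export
bindSampleSets <- function(sets, role = NULL) {
  stopifnot(length(sets) >= 1L)
  d <- dim(sets[[1]]@eeg)[1:2]
  for (s in sets) {
    if (!identical(dim(s@eeg)[1:2], d)) stop("sample sets have mismatched dimensions")
  }
  new("PairedSampleSet",
      eeg = array(unlist(lapply(sets, function(s) s@eeg)),
                  c(d, sum(vapply(sets, nSamples, 1L)))),
      emg = array(unlist(lapply(sets, function(s) s@emg)),
                  c(d, sum(vapply(sets, nSamples, 1L)))),
      label = unlist(lapply(sets, function(s) s@label)),
      subjectId = unlist(lapply(sets, function(s) s@subjectId)),
      windowIndex = unlist(lapply(sets, function(s) s@windowIndex)),
      phase = unlist(lapply(sets, function(s) s@phase)),
      role = if (is.null(role)) sets[[1]]@role else role,
      augmented = any(vapply(sets, function(s) s@augmented, TRUE)))
}

#' Change the provenance tag of a sample set
#'
#' @param x a \linkS4class{PairedSampleSet}.
#' @param role "unsplit", "train" or "test".
#' @return the retagged set.
#' @export
setSampleRole <- function(x, role) {
  x@role <- role
  validObject(x)
  x
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("%s Recording: %d channels x %d samples @ %g Hz (subject %s)\n",
              object@modality, nrow(object@data), ncol(object@data),
              object@rateHz, object@subjectId))
})

setMethod("show", "PairedSampleSet", function(object) {
  n <- nSamples(object)
  cat(sprintf("PairedSampleSet: %d samples, %d channels x %d points per window\n",
              n, dim(object@eeg)[1], dim(object@eeg)[2]))
  if (n > 0) {
    tb <- table(factor(object@label, levels = 0:2))
    cat(sprintf("  labels: low=%d moderate=%d high=%d | role=%s%s\n",
                tb[1], tb[2], tb[3], object@role,
                if (object@augmented) " (augmented)" else ""))
  }
})

#' Write / read a paired-sample dataset
#'
#' Datasets are stored as single-file RDS archives holding the signal arrays,
#' labels and sample metadata.
#'
#' @param x a \linkS4class{PairedSampleSet}.
#' @param path file path.
#' @return \code{writePairedSampleSet} returns \code{path} invisibly;
#'   \code{readPairedSampleSet} returns the \linkS4class{PairedSampleSet}.
#' @export
writePairedSampleSet <- function(x, path) {
  stopifnot(is(x, "PairedSampleSet"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname writePairedSampleSet
#' @export
readPairedSampleSet <- function(path) {
  x <- readRDS(path)
  if (!is(x, "PairedSampleSet")) stop("file does not contain a PairedSampleSet")
  validObject(x)
  x
}
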
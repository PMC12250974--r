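#' @include AllClasses.R
NULL

#' Number of samples / channels in a container
#'
#' @param x a \linkS4class{Recording} or \linkS4class{PairedSampleSet}.
#' @return an integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setGeneric("channelCount", function(x) standardGeneric("channelCount"))

#' Accessors for paired sample sets
#'
#' @param x a \linkS4class{PairedSampleSet}.
#' @return the corresponding slot content.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname eegData
#' @export
setGeneric("emgData", function(x) standardGeneric("emgData"))

#' @rdname eegData
#' @export
setGeneric("labels3", function(x) standardGeneric("labels3"))

#' @rdname eegData
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname eegData
#' @export
setGeneric("windowIndices", function(x) standardGeneric("windowIndices"))

#' @rdname eegData
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname eegData
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))

#' Augment a training set
#'
#' @param x a \linkS4class{PairedSampleSet} with role "train" or "unsplit".
#' @param cfg an \linkS4class{AugmentConfig}.
#' @return the augmented \linkS4class{PairedSampleSet}.
#' @export
setGeneric("augmentSet", function(x, cfg = augmentConfig()) standardGeneric("augmentSet"))

#' Predict workload labels
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param data a \linkS4class{PairedSampleSet}.
#' @param ... further arguments (batch size).
#' @return an integer vector of labels in {0,1,2}.
#' @export
setGeneric("predictLabels", function(model, data, ...) standardGeneric("predictLabels"))
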
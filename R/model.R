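#' @include AllClasses.R
NULL

#' Construct a ModelConfig
#'
#' @param D common feature dimension both modalities are projected to.
#' @param kEeg,kEmg odd temporal kernel sizes of the Conv1D projections.
#' @param nHeads number of attention heads (must divide D).
#' @param nLayers number of transformer encoder blocks per branch.
#' @param ffnHidden hidden width of the position-wise feed-forward network.
#' @param trunkChannels channel count of the shared fusion trunk.
#' @param nFusionBlocks number of ConvNeXt-style blocks after the first custom
#'   block (3 in the reference configuration).
#' @param fcHidden hidden width of the two-layer classifier heads.
#' @param nClasses number of workload classes.
#' @param nModalities number of modalities (2: EEG and EMG).
#' @param grlLambda gradient-reversal scale lambda, >= 0.
#' @param standardBlock FALSE (default) places the residual and LayerNorm
#'   around the feed-forward applied to the attention output only; TRUE uses
#'   the conventional two-residual transformer block.
#' @param useTransformer FALSE bypasses positional encoding and attention so
#'   Conv1D features feed the trunk directly.
#' @param useAdversary FALSE removes the modal classifier and gradient
#'   reversal (plain concatenation fusion).
#' @param modality "both", "eeg" or "emg" (single-branch variants).
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(D = 8L, kEeg = 3L, kEmg = 3L, nHeads = 4L,
                        nLayers = 1L, ffnHidden = 32L, trunkChannels = 4L,
                        nFusionBlocks = 3L, fcHidden = 32L, nClasses = 3L,
                        nModalities = 2L, grlLambda = 1.0,
                        standardBlock = FALSE, useTransformer = TRUE,
                        useAdversary = TRUE, modality = "both") {
  new("ModelConfig", D = as.integer(D), kEeg = as.integer(kEeg),
      kEmg = as.integer(kEmg), nHeads = as.integer(nHeads),
      nLayers = as.integer(nLayers), ffnHidden = as.integer(ffnHidden),
      trunkChannels = as.integer(trunkChannels),
      nFusionBlocks = as.integer(nFusionBlocks), fcHidden = as.integer(fcHidden),
      nClasses = as.integer(nClasses), nModalities = as.integer(nModalities),
      grlLambda = grlLambda, standardBlock = standardBlock,
      useTransformer = useTransformer, useAdversary = useAdversary,
      modality = modality)
}

# plain-list view of a ModelConfig for the compiled core
cfgAsList <- function(cfg) {
  list(D = cfg@D, kEeg = cfg@kEeg, kEmg = cfg@kEmg, nHeads = cfg@nHeads,
       nLayers = cfg@nLayers, ffnHidden = cfg@ffnHidden,
       trunkChannels = cfg@trunkChannels, nFusionBlocks = cfg@nFusionBlocks,
       fcHidden = cfg@fcHidden, nClasses = cfg@nClasses,
       grlLambda = cfg@grlLambda, standardBlock = cfg@standardBlock,
       useTransformer = cfg@useTransformer, useAdversary = cfg@useAdversary,
       modality = cfg@modality)
}

#' Sinusoidal positional encoding
#'
#' Entry [pos, 2k] = sin(pos / 10000^(2k/D)) and [pos, 2k+1] = cos of the
#' same argument, with pos and k both 0-based (pos = 0..L-1,
#' k = 0..D/2-1), so every column of the L x D matrix is defined.
#'
#' @param L sequence length.
#' @param D feature dimension (even).
#' @return an L x D matrix with entries in [-1, 1].
#' @examples
#' positionalEncoding(4, 6)[1, ]  # row for pos = 0: 0, 1, 0, 1, 0, 1
#' @export
positionalEncoding <- function(L, D) {
  if (D %% 2L != 0L) stop("invalid config: positional encoding needs even D")
  cpp_positional_encoding(L, D)
}

#' Conv1D projection of a signal window
#'
#' Projects a channels x samples window into a length-preserving sequence of
#' D-dimensional feature vectors with a same-padded 1-D temporal convolution
#' (odd kernel). EEG and EMG branches hold separate weights but share D.
#'
#' @param x channels x samples matrix.
#' @param weights D x channels x kernel array.
#' @param bias length-D numeric vector.
#' @return samples x D matrix (a feature sequence).
#' @export
projectConv1d <- function(x, weights, bias) {
  x <- as.matrix(x)
  k <- dim(weights)[3]
  if (k %% 2L == 0L) stop("invalid config: kernel must be odd")
  if (k > ncol(x)) stop("invalid config: kernel longer than the window")
  cpp_conv1d(x, weights, bias)
}

#' Multi-head self-attention over a feature sequence
#'
#' Queries, keys and values are linear maps of the input; per head the
#' attention weights are the row-softmax of Q K' / sqrt(dK) with dK = D/nHeads,
#' head outputs are concatenated and linearly recombined.
#'
#' @param O L x D feature-sequence matrix.
#' @param weights list with D x D matrices \code{Wq}, \code{Wk}, \code{Wv},
#'   \code{Wo} and length-D vectors \code{bq}, \code{bk}, \code{bv}, \code{bo}.
#' @param nHeads number of heads.
#' @return list with \code{out} (L x D) and \code{attn}
#'   (L x L x nHeads attention weights; every row sums to 1).
#' @export
multiHeadSelfAttention <- function(O, weights, nHeads) {
  D <- ncol(O)
  if (D %% nHeads != 0L) stop("invalid config: D not divisible by nHeads")
  cpp_attention(O, weights$Wq, weights$bq, weights$Wk, weights$bk,
                weights$Wv, weights$bv, weights$Wo, weights$bo, nHeads)
}

#' Gradient reversal (forward view)
#'
#' The gradient-reversal layer is the identity in the forward pass; during
#' backpropagation it multiplies incoming gradients by -lambda, which turns
#' the minimisation of the modal-classification loss into a maximisation for
#' everything upstream of the layer (the adversarial min-max in a single
#' minimisation). The backward behaviour lives in the training core; this
#' helper exposes the forward contract.
#'
#' @param x numeric vector or matrix of fused features.
#' @param lambda reversal scale, >= 0 (unused in the forward pass).
#' @return \code{x}, unchanged.
#' @export
gradientReversal <- function(x, lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  x
}

#' Initialise model parameters
#'
#' He/Glorot-style random initialisation of every layer for a given input
#' geometry. Batch-norm running statistics start at mean 0 / variance 1.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param nChannels input channels per modality.
#' @param windowLength samples per window.
#' @param seed RNG seed.
#' @return a named list of parameter arrays.
#' @export
initializeModel <- function(cfg, nChannels, windowLength, seed = 1L) {
  set.seed(seed)
  D <- cfg@D; ch <- cfg@trunkChannels
  Lp <- windowLength %/% 2L; Dp <- D %/% 2L
  Fdim <- ch * Lp * Dp
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  he <- function(dims, fanIn) array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
  p <- list()
  branch <- function(pre, k) {
    b <- list()
    b[[paste0(pre, "_convW")]] <- he(c(D, nChannels, k), nChannels * k)
    b[[paste0(pre, "_convb")]] <- numeric(D)
    if (cfg@useTransformer) {
      for (l in seq_len(cfg@nLayers)) {
        nm <- function(part) sprintf("%s_l%d_%s", pre, l, part)
        for (w in c("Wq", "Wk", "Wv", "Wo")) b[[nm(w)]] <- glorot(D, D)
        for (v in c("bq", "bk", "bv", "bo")) b[[nm(v)]] <- numeric(D)
        b[[nm("W1")]] <- glorot(D, cfg@ffnHidden)
        b[[nm("b1")]] <- numeric(cfg@ffnHidden)
        b[[nm("W2")]] <- glorot(cfg@ffnHidden, D)
        b[[nm("b2")]] <- numeric(D)
        b[[nm("ln1g")]] <- rep(1, D); b[[nm("ln1b")]] <- numeric(D)
        b[[nm("ln2g")]] <- rep(1, D); b[[nm("ln2b")]] <- numeric(D)
      }
    }
    b
  }
  if (cfg@modality != "emg") p <- c(p, branch("e", cfg@kEeg))
  if (cfg@modality != "eeg") p <- c(p, branch("m", cfg@kEmg))
  p$trunk_convW <- he(c(3, 3, ch), 9)
  p$trunk_convb <- numeric(ch)
  p$trunk_bn_g <- rep(1, ch); p$trunk_bn_b <- numeric(ch)
  p$trunk_bn_rm <- numeric(ch); p$trunk_bn_rv <- rep(1, ch)
  for (j in seq_len(cfg@nFusionBlocks)) {
    p[[sprintf("cnx%d_W", j)]] <- he(c(7, 7, ch), 49)
    p[[sprintf("cnx%d_b", j)]] <- numeric(ch)
    p[[sprintf("cnx%d_lng", j)]] <- rep(1, ch)
    p[[sprintf("cnx%d_lnb", j)]] <- numeric(ch)
  }
  clsIn <- if (cfg@modality == "both") 2L * Fdim else Fdim
  p$cls_W1 <- glorot(clsIn, cfg@fcHidden)
  p$cls_b1 <- numeric(cfg@fcHidden)
  p$cls_W2 <- glorot(cfg@fcHidden, cfg@nClasses)
  p$cls_b2 <- numeric(cfg@nClasses)
  if (cfg@useAdversary && cfg@modality == "both") {
    p$mod_W1 <- glorot(Fdim, cfg@fcHidden)
    p$mod_b1 <- numeric(cfg@fcHidden)
    p$mod_W2 <- glorot(cfg@fcHidden, cfg@nModalities)
    p$mod_b2 <- numeric(cfg@nModalities)
  }
  p
}

# empty 3-d array placeholder for an absent modality
emptyCube <- function() array(0, c(0L, 0L, 0L))

#' Forward pass of a trained model
#'
#' Runs the network in inference mode (batch-norm uses running statistics; the
#' modal classifier is bypassed for the decision) and returns class
#' probabilities and fused features.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param data a \linkS4class{PairedSampleSet}.
#' @param batchSize samples per forward chunk.
#' @param training use batch statistics in the trunk batch-norm, as during
#'   training (the representation the adversarial game acts on); FALSE uses
#'   the stored running statistics (deployment inference).
#' @return list with \code{probs} (N x nClasses), \code{fusedEeg},
#'   \code{fusedEmg} (N x F or empty), \code{modalProbsEeg},
#'   \code{modalProbsEmg}, and \code{attnCalls}.
#' @export
forwardPass <- function(model, data, batchSize = 256L, training = FALSE) {
  cfg <- model@modelConfig
  cl <- cfgAsList(cfg)
  n <- nSamples(data)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batchSize))
  parts <- lapply(idx, function(i) {
    ee <- if (cfg@modality != "emg") data@eeg[, , i, drop = FALSE] else emptyCube()
    mm <- if (cfg@modality != "eeg") data@emg[, , i, drop = FALSE] else emptyCube()
    cpp_forward(model@params, cl, ee, mm, training)
  })
  bindRows <- function(name) do.call(rbind, lapply(parts, `[[`, name))
  list(probs = bindRows("probs"),
       fusedEeg = bindRows("fusedEeg"),
       fusedEmg = bindRows("fusedEmg"),
       modalProbsEeg = bindRows("modalProbsEeg"),
       modalProbsEmg = bindRows("modalProbsEmg"),
       attnCalls = sum(vapply(parts, `[[`, 1L, "attnCalls")))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig: D=%d heads=%d layers=%d ffn=%d | trunk %dch x %d ConvNeXt blocks",
    " | fc=%d classes=%d\n  modality=%s transformer=%s adversary=%s (lambda=%g)%s\n"),
    object@D, object@nHeads, object@nLayers, object@ffnHidden,
    object@trunkChannels, object@nFusionBlocks, object@fcHidden,
    object@nClasses, object@modality, object@useTransformer,
    object@useAdversary, object@grlLambda,
    if (object@standardBlock) " [standard blocks]" else ""))
})

#' Layer-by-layer shape propagation
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param nChannels input channels.
#' @param windowLength samples per window.
#' @return a data.frame of stage names and output shapes (also printed).
#' @export
describeModel <- function(cfg, nChannels = 32L, windowLength = 1000L) {
  L <- windowLength; D <- cfg@D; ch <- cfg@trunkChannels
  Lp <- L %/% 2L; Dp <- D %/% 2L
  Fdim <- ch * Lp * Dp
  rows <- list(
    c("input (per modality)", sprintf("%d x %d", nChannels, L)),
    c("conv1d projection", sprintf("%d x %d", L, D)))
  if (cfg@useTransformer) {
    rows <- c(rows, list(
      c("+ positional encoding", sprintf("%d x %d", L, D)),
      c(sprintf("%d transformer block(s)", cfg@nLayers), sprintf("%d x %d", L, D))))
  }
  rows <- c(rows, list(
    c(sprintf("trunk conv3x3 (%dch) + BN + ReLU", ch), sprintf("%d x %d x %d", ch, L, D)),
    c("max-pool 2x2 /2", sprintf("%d x %d x %d", ch, Lp, Dp)),
    c(sprintf("%d ConvNeXt-style block(s)", cfg@nFusionBlocks), sprintf("%d x %d x %d", ch, Lp, Dp)),
    c("flatten", sprintf("%d", Fdim)),
    c("workload classifier", sprintf("%d -> %d -> %d",
        if (cfg@modality == "both") 2L * Fdim else Fdim, cfg@fcHidden, cfg@nClasses))))
  if (cfg@useAdversary && cfg@modality == "both") {
    rows <- c(rows, list(c("modal classifier (GRL, training only)",
                           sprintf("%d -> %d -> 2", Fdim, cfg@fcHidden))))
  }
  df <- data.frame(stage = vapply(rows, `[`, "", 1),
                   shape = vapply(rows, `[`, "", 2))
  print(df, right = FALSE, row.names = FALSE)
  invisible(df)
}
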
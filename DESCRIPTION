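Package: neurofuse
Title: Adversarial Multimodal Fusion of EEG and EMG for Mental Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-branch Transformer feature extraction with domain-adversarial
    modality alignment for three-level mental-workload classification from
    paired EEG/EMG windows. Implements the full pipeline: zero-phase Butterworth
    band-pass preprocessing, non-overlapping windowing with interleaved EEG
    downsampling and EEG/EMG pairing, flip/noise training-set augmentation,
    per-modality Conv1D + sinusoidal positional encoding + multi-head
    self-attention feature extractors, a shared convolutional fusion trunk
    (custom block plus ConvNeXt-style blocks), a gradient-reversal modal
    classifier, joint adversarial training with element-wise gradient clipping,
    stratified five-fold cross-validation with leakage guards, ablation
    variants, and a synthetic paired-signal generator with a controllable
    inter-modality distribution shift for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    yaml,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'paired-samples.R'
    'augmentation.R'
    'model.R'
    'training.R'
    'evaluation.R'
    'neurofuse-package.R'
    'probe.R'
    'preprocessing.R'
    'simulate.R'
    'pipeline.R'
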
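Package: neurodecline
Title: Multimodal Prediction of Domain-Level Cognitive Decline on the
    Alzheimer's Continuum
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a multimodal learning framework for predicting
    domain-level cognitive decline and future clinical diagnosis on the
    Alzheimer's disease continuum. Provides three representations of
    template-space neuroimaging volumes (ROI-aggregated tabular features,
    downsampled 3D volumes, and atlas-parcellation brain graphs with
    graphical-lasso connectivity), cognitive composite construction from
    longitudinal neuropsychological batteries (imputation, one-factor
    measurement models, reference-anchored rescaling, normative age and
    education adjustment), decline-target construction (per-domain slopes,
    normative 5th-percentile decliner thresholds, horizon diagnosis labels),
    masked multitask modality pre-training, attention-based late fusion with
    fine-tuning, evaluation metrics, and a seeded synthetic cohort generator
    emulating an ADNI-like longitudinal study at desk scale.
    Neural-network components (feed-forward, 3D convolutional, and graph
    neural networks with multi-head attention fusion) run on a compact
    built-in compute engine with analytic backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
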
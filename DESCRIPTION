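Package: wheatfusion
Title: Multi-Source Data Fusion for Winter Wheat Yield Prediction
Version: 0.1.0
Authors@R: person("Analytics", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts winter-wheat yield per unit area from multi-source
    seasonal inputs: monthly satellite vegetation indices (NDVI, EVI),
    monthly climate variables, dynamic soil moisture/temperature series and
    static soil physicochemical properties. Per-source temporal features are
    extracted with sliding-window stacked GRUs and convolutional residual
    blocks, fused through a triple cross-attention mechanism built on
    efficient additive attention, and decoded by a dual-branch Transformer
    encoder (multi-head self-attention in parallel with graph attention)
    followed by a Fourier analysis network. Includes a seeded synthetic
    agro-season generator with a known ground-truth yield function, the
    year-based train/validation/test split protocol, training with early
    stopping and plateau learning-rate decay, evaluation metrics
    (MAE, RMSE, MAPE, MSPE, R-squared), ablation and time-window study
    harnesses, and a command-line interface. All networks run on a small
    built-in reverse-mode automatic differentiation engine, so the package
    has no deep-learning framework dependency.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
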
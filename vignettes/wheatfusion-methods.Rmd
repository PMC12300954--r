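---
title: "Multi-source fusion for winter-wheat yield prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source fusion for winter-wheat yield prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatfusion)
```

## The problem

County-level winter-wheat yield (kg/hm²) responds jointly to canopy
development (observable as monthly NDVI/EVI), weather over the growing
season (seven monthly climate variables), and soil (monthly moisture and
temperature at two depths, plus sixteen static physicochemical
properties). The growing season runs October through June — nine monthly
time steps. The sources differ in dynamics and scale, and the yield
response includes cross-source interactions (canopy vigor matters more
when water is available), so this package fuses the sources with
cross-attention rather than simple concatenation.

`wheatfusion` implements the full pipeline: per-source deep feature
extraction, triple cross-attention fusion, and a Transformer-style
prediction head — plus a seeded synthetic generator of season records,
because the motivating study's regional dataset is private. Everything
runs on a small built-in reverse-mode autodiff engine (`R/autograd.R`):
no deep-learning framework for R is assumed, and gradients of every
fused operation are verified against central differences in the test
suite.

## Model

**Per-source extraction.** Each dynamic source (remote sensing, climate,
dynamic soil) passes through a temporal feature extractor (TFE): the
9-month series is cut into sliding windows (length 3, stride 1 by
default, so 7 windows), a 2-layer GRU stack runs over each window and
its final hidden state becomes that window's token, and a convolutional
residual block (CRB: conv → layer norm → GELU → conv, plus a skip path,
1×1-projected when channel counts change) refines the token sequence.
The static soil vector is lifted linearly to the model dimension and
passed through a kernel-1 CRB, contributing one extra token that is
concatenated onto the dynamic-soil tokens. All sources emit `d_model`
channels (64 by default).

**Triple cross-attention fusion (TCAFM).** For each of the six ordered
source pairs, queries from one source and keys from the other are
produced by learned linear maps and combined by efficient additive
attention — a linear-complexity form in which per-token scores
`a_i = Q_i·w/√d` are softmax-normalized, a global query `g = Σ α_i Q_i`
modulates the keys elementwise, and each output token is
`layernorm(Q_i + Linear(g ⊙ K_i))`. The six outputs are concatenated by
channel (6·`d_attn` channels), refined by a CRB down to `d_model`, and
gated multiplicatively by
`layernorm(sigmoid(Linear(relu(dropout(Linear(x))))))`. Because the
sources can emit different token counts (soil carries the extra static
token), token sequences are first aligned to the largest count by linear
resampling.

**Prediction head.** Three covariate tokens — year (linear map to
[0, 1] over the training span), region (one-hot over the region codes),
and planting area (train z-score), each lifted to `d_model` — are
prepended to the fused tokens; sinusoidal positional encodings are
added. A 2-layer dual-branch encoder processes the sequence: multi-head
self-attention (global dependencies) in parallel with single-layer graph
attention over a local token graph (sliding neighborhood of radius 2
with self-loops), merged by elementwise sum, each sub-layer wrapped in
residual + layer norm with a position-wise feed-forward network. Tokens
are mean-pooled and decoded by two Fourier-analysis-network layers —
`[cos(W_p x) ‖ sin(W_p x) ‖ gelu(B̄ + W̄ x)]` — and a linear head. The
output is de-normalized to kg/hm² with training-set statistics.

## Normalization

The default is reversible instance normalization of the dynamic series:
each variable of each record is centered and scaled over its nine
months. Because a scalar-yield head cannot "restore" the statistics at
the output the way a forecasting model would, the per-record (mean, sd)
vector of each source is re-injected as a learned, broadcast-added
embedding on that source's tokens — nothing is discarded, which matters
here because the season-mean NDVI level carries most of the yield
signal. A plain `global` mode (per-feature train z-scores) is available
via `model_config(norm_mode = "global")`. Static soil, planting area and
the yield label always use train-set z-scores, and the normalizer is fit
on the training split only.

## Training protocol

Adam, learning rate 1e-3, batch size 8, MAE loss on normalized yields,
up to 1000 epochs. Early stopping halts training after 20 consecutive
epochs without validation improvement (an improvement is a decrease
greater than 1e-6); the learning rate is multiplied by 0.9 whenever the
validation loss stalls for 10 epochs; the best-validation parameter
snapshot is restored at the end. One source text gives patience 20 and
another (a pseudocode listing) 40; we follow 20, which the prose states
twice. All shuffling and initialization is seeded: one seed gives a
bit-identical loss trajectory.

One caveat the convergence studies exposed: the MAE subgradient does not
vanish near an optimum, so with the plateau rule alone (which only fires
when validation stalls, and validation keeps creeping down) the training
loss settles into an oscillation floor proportional to the learning
rate — around 5% of the yield sd at lr 1e-3. `train_config()` therefore
offers `lr_step_every`, an unconditional step schedule used by the
zero-noise overfitting check to drive the train MAE below 1% of the
yield sd; the plateau protocol remains the default everywhere else. The
same check uses `norm_mode = "global"`, which converges measurably
faster than instance normalization on the level-dependent quadratic
temperature term of the synthetic response.

The split protocol holds out all records from the test years (2021 and
2022 by default) and divides the rest 8:2 into train and validation.
The validation draw is stratified by region — each region contributes
about 20% of its non-test seasons — so that validation difficulty is not
confounded with region identity; the global 8:2 ratio is enforced to
within one record by largest-remainder allocation.

## The synthetic world

`generate_dataset()` emulates the schema of the private study data: 196
regions × 22 seasons (2001–2022) by default. Stated choices, fixed once:

* **Vegetation**: NDVI follows a smooth Gaussian bump over the month
  index with a region-specific peak position drawn in March–April
  (jointing–heading), peak height ~ N(0.65, 0.06) with a yearly vigor
  multiplier ~ N(1, 0.08), and base level ~ U(0.12, 0.18). Curves are
  noise-free in the month direction, so unimodality holds by
  construction. EVI is an affine companion of NDVI.
* **Climate**: each of the seven variables is an annual sinusoid peaking
  in July plus Gaussian noise, with means/amplitudes at plausible
  magnitudes for the North China Plain (e.g. air temperature 9 ± 12 °C
  annual swing, precipitation ~1.4 mm/day); regions get persistent
  precipitation and temperature offsets.
* **Soil**: dynamic moisture tracks precipitation anomalies and the
  seasonal cycle; soil temperatures are damped versions of air
  temperature. The sixteen static properties are per-region draws from
  fixed normals (e.g. pH 7.5 ± 0.5) and are constant across years.
* **Yield**: `y = b0 + b1·Σ NDVI + f(climate) + w·c·Σ NDVI·precip +
  region effect + 40·(year − 2001) + N(0, noise_sd)`, where `f` is a
  quadratic temperature-optimum term plus a precipitation term. The
  interaction weight `w` (default 1) controls the cross-source term that
  additive fusion cannot represent. Coefficients were calibrated once so
  the yield distribution has mean ≈ 6000 and sd ≈ 1500 kg/hm², matching
  the magnitudes of published county-level error tables; the default
  noise sd is 300 kg/hm² (~5% of the mean), a realistic statistical
  reporting error. The generator returns its coefficients, and
  `yield_closed_form()` reproduces the deterministic part exactly —
  the basis of the recovery tests.

What the generator does **not** emulate: spatial correlation between
regions, raster/pixel structure, satellite retrieval artifacts beyond
simple missingness, multi-year autocorrelation of weather, and any real
geography. A green test therefore establishes that the architecture,
optimization and protocol work as specified and can recover a known
cross-source response — not that the model attains any particular skill
on real data.

`inject_missing()` masks an exact count of interior monthly cells
(never the first or last month, so the linear interpolation of
`interpolate_missing()` is always defined), emulating the small number
of severely missing time nodes in raw extractions.

## Numerical choices

* Layer norm uses population variance with ε = 1e-5; the attention and
  gate layer norms are parameter-free, the encoder's carry affine
  parameters.
* GELU is exact (`x·Φ(x)`), not the tanh approximation.
* Softmax subtracts the row maximum before exponentiation.
* MAE's subgradient at zero is taken as 0.
* Dropout (rate 0.1) applies only inside the fusion gate and only in
  training mode; all forward passes in evaluation mode are pure.
* Glorot-uniform initialization, seeded; parameters materialize on the
  first traced forward pass, so initialization is a deterministic
  function of the model seed and the architecture.
* Degenerate constant features receive scale 1 rather than 0.
* Stage windows shorter than the TFE window clamp the window to the
  series length (T1/T3/T4 have 2 months; the default window is 3).

## Open design points and how they were resolved

The architecture description leaves several details open; the package
pins them as follows, as its own design choices: TFE weights are
independent per source; each window's token is the final top-layer GRU
hidden state; the six cross-attention pairs have independent Q/K
projections; token alignment uses linear resampling; the dual branches
merge by sum (a `concat_project` option exists); the token graph is a
radius-2 sliding neighborhood (a `full` option exists); pooling is the
token mean; FAN widths are d_p = 16, d_p̄ = 32 with GELU. The ablation
flags (`use_tfe`, `use_gat`, `fusion`, `sources`) switch these
components without code forks, which is what makes the ablation grids
(4-row TFE/GAT design, 8-row fusion design) drop-in comparisons.

## Limitations

Training runs on one CPU through an interpreted tape; a full-size run
(4312 records, d_model 64) takes minutes per epoch, so the worked
examples, tests and the acceptance script use reduced dimensions,
larger batches and few epochs, and state so where they do. The engine
supports exactly what the model needs (dense matrices, the ops in
`R/autograd.R`) and is not a general framework. Uncertainty
quantification, multi-step forecasting and raster-level inputs are out
of scope.
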
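# wheatfusion

Multi-source data fusion for winter-wheat yield prediction in R.

County-level winter-wheat yield (kg/hm²) is driven jointly by canopy
development, weather and soil. This package predicts yield per unit area
from the four inputs such studies assemble per region and growing season
(October–June, nine monthly steps):

* monthly satellite vegetation indices (NDVI, EVI),
* seven monthly climate variables (evapotranspiration, radiation fluxes,
  pressure, precipitation, temperature, wind),
* dynamic soil moisture/temperature at two depths plus sixteen static
  physicochemical soil properties,
* spatio-temporal covariates: year, region code, planting area.

## The model

Each dynamic source passes through a **temporal feature extractor**
(sliding windows over the months → stacked GRUs per window → a
convolutional residual block over the window tokens); the static soil
vector is lifted and refined by a kernel-1 residual block and joins the
dynamic-soil tokens. The three source embeddings interact through a
**triple cross-attention fusion mechanism**: for each of the six ordered
source pairs, efficient additive attention (linear in token count)
computes

    a_i = Q_i·w / √d,   α = softmax(a),   g = Σ_i α_i Q_i,
    out_i = layernorm(Q_i + Linear(g ⊙ K_i)),

the six outputs are concatenated by channel, refined by a residual
block, and gated by `layernorm(sigmoid(MLP(x)))`. A 2-layer dual-branch
Transformer encoder (multi-head self-attention ∥ graph attention over a
local token graph) processes the fused tokens together with three
covariate tokens and sinusoidal positional encodings, and a two-layer
Fourier analysis network — `[cos(W_p x) ‖ sin(W_p x) ‖ σ(B̄ + W̄ x)]` —
decodes the pooled representation into ŷ (kg/hm²).

Training follows the reference protocol: Adam, lr 1e-3, batch 8, MAE
loss, early stop after 20 flat validation epochs, learning rate × 0.9
after a 10-epoch plateau, best-validation checkpoint restored. Metrics:
MAE, RMSE, MAPE, MSPE, R².

Everything runs on a small built-in reverse-mode autodiff engine
(`R/autograd.R`) whose gradients are finite-difference-verified in the
test suite — no Python or deep-learning framework required.

Because the regional dataset that motivated this architecture is
private, the package includes a **seeded synthetic season generator**
with a known ground-truth yield function (smooth unimodal NDVI curves
peaking at jointing–heading, sinusoidal climate, per-region static soil,
a remote-sensing × precipitation interaction, region effects, a year
trend and Gaussian noise). Tests recover that known response end to end;
see the methods vignette (`vignettes/wheatfusion-methods.Rmd`) for what
a green test does and does not establish.

## Worked example

```r
library(wheatfusion)

ds    <- generate_dataset(sim_config(n_regions = 20, years = 2010:2022, seed = 42))
split <- split_dataset(ds, test_years = c(2021, 2022), seed = 1)
ds
#> <wf_dataset> 260 records (20 regions x 13 years); yield mean 5926, sd 1617 kg/hm^2
split
#> <wf_split> train 176 / val 44 / test 40 (seed 1)

cfg   <- model_config(d_model = 16, d_attn = 16, n_heads = 2, gru_hidden = 16,
                      ffn_dim = 32, fan_dp = 8, fan_dpbar = 16)
model <- wf_model(cfg, ds, split, seed = 1)
model
#> <wf_model> d_model 16, 3 sources, fusion tcafm, 40385 parameters

model   <- train(model, ds, split, train_config(batch = 32, max_epochs = 15, seed = 1))
evaluate(model, ds, split$test)
#> MAE 869.54  RMSE 1169.38  MAPE 13.46%  MSPE 2.9157  R2 0.504  (n = 40)
```

Fifteen epochs at this reduced scale already explain half the yield
variance of the held-out 2021–2022 seasons; the acceptance suite trains
the same architecture on the full 196-region × 22-year world (4312
records) and reaches test R² ≥ 0.8 while beating a train-mean predictor's
MAE by more than half. Per-source embeddings are also exposed directly:

```r
embs <- extract_all(ds$records[[1]], model)
sapply(embs, nrow)
#> rs cl so
#>  7  7  8    # 7 window tokens; soil adds one static token
```

Ablation and study harnesses mirror the reference experiment designs:
`run_ablation_grid(ds, split, "tfe_gat")` (4 rows: TFE/graph-attention
on–off), `run_ablation_grid(ds, split, "fusion")` (8 rows: single
sources, concat/add/avg/max, cross-attention fusion), and
`run_window_study(ds, split, "prefix" | "stages")` (first 3..9 months;
growth stages T1–T4).

## Command line

```sh
Rscript -e 'quit(status = wheatfusion::wf_main())' \
  simulate --out data/ --seed 7 --n-regions 20 --years 2010:2022
Rscript -e 'quit(status = wheatfusion::wf_main())' \
  train --data data/dataset.csv --out run/ --epochs 30 --seed 1
Rscript -e 'quit(status = wheatfusion::wf_main())' \
  evaluate --model run/ --data data/dataset.csv --out run/metrics.csv
```

Each run writes a resolved-config snapshot next to its outputs; JSON
configs may be passed with `--config` (flags win).

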
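# Shared fixtures: small seeded worlds and model configurations that keep
# unit tests fast. All randomness is pinned.

wf <- asNamespace("wheatfusion")

tiny_dataset <- function(n_regions = 6L, years = 2018:2022, seed = 5L,
                         noise_sd = 300, interaction_weight = 1) {
  suppressWarnings(generate_dataset(sim_config(
    n_regions = n_regions, years = years, test_years = c(2021L, 2022L),
    noise_sd = noise_sd, interaction_weight = interaction_weight,
    seed = seed)))
}

tiny_model_config <- function(...) {
  model_config(d_model = 8L, d_attn = 8L, n_heads = 2L, gru_hidden = 8L,
               ffn_dim = 16L, fan_dp = 4L, fan_dpbar = 8L, ...)
}

# Set every parameter whose name matches `pattern` to `value`.
set_params <- function(store, pattern, value = 0) {
  for (nm in grep(pattern, ls(store), value = TRUE)) {
    store[[nm]][] <- value
  }
  invisible(store)
}

# Reference row softmax used by several oracles.
ref_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Reference parameter-free layer norm (population variance, eps 1e-5).
ref_layernorm <- function(x, eps = 1e-5) {
  t(apply(x, 1L, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
}

ref_gelu <- function(x) x * stats::pnorm(x)
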
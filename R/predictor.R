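# Yield prediction head.
#
# The fused feature tokens are prepended with three covariate tokens
# (time, one-hot region, normalized planting area, each lifted to the
# model dimension), summed with sinusoidal positional encodings, passed
# through a 2-layer dual-branch encoder (multi-head self-attention in
# parallel with graph attention over a local token graph), mean-pooled,
# and decoded by two Fourier-analysis-network layers and a linear head.
# Predictions are de-normalized back to kg/hm^2.

#' Model configuration
#'
#' Pins every hyperparameter of the architecture in one place.
#'
#' @param d_model shared embedding dimension of the three sources.
#' @param d_attn per-pair dimension of the fusion cross-attention.
#' @param n_heads self-attention heads (must divide `d_model`).
#' @param window,stride sliding-window length/stride of the TFE (the
#'   window is clamped to the series length for short stage subsets).
#' @param gru_layers,gru_hidden GRU stack depth and hidden width.
#' @param crb_blocks,crb_kernel residual block count and kernel width.
#' @param ffn_dim encoder feed-forward width.
#' @param fan_dp,fan_dpbar periodic / non-periodic widths of each FAN
#'   layer (output width is `2*fan_dp + fan_dpbar`).
#' @param graph token-graph rule: `"window_k"` (sliding neighborhood of
#'   radius `graph_radius` plus self-loops) or `"full"`.
#' @param graph_radius neighborhood radius for `"window_k"`.
#' @param merge dual-branch combination: `"sum"` or `"concat_project"`.
#' @param encoder_layers number of encoder layers.
#' @param dropout dropout rate (fusion gate; training mode only).
#' @param use_tfe replace the TFE by a per-month linear lift when FALSE
#'   (ablation experiment).
#' @param use_gat drop the graph-attention branch when FALSE, leaving a
#'   vanilla Transformer encoder (ablation experiment).
#' @param fusion `"tcafm"` or a baseline: `"concat"`, `"add"`, `"avg"`,
#'   `"max"`.
#' @param sources subset of `c("rs", "cl", "so")` fed to the model
#'   (single-source ablations).
#' @param norm_mode `"instance"` (reversible instance normalization with
#'   statistic re-injection) or `"global"` (train z-scores).
#' @return object of class `wf_model_config`.
#' @export
model_config <- function(d_model = 64L, d_attn = 64L, n_heads = 4L,
                         window = 3L, stride = 1L, gru_layers = 2L,
                         gru_hidden = 64L, crb_blocks = 2L, crb_kernel = 3L,
                         ffn_dim = 128L, fan_dp = 16L, fan_dpbar = 32L,
                         graph = c("window_k", "full"), graph_radius = 2L,
                         merge = c("sum", "concat_project"),
                         encoder_layers = 2L, dropout = 0.1,
                         use_tfe = TRUE, use_gat = TRUE, fusion = "tcafm",
                         sources = c("rs", "cl", "so"),
                         norm_mode = c("instance", "global")) {
  graph <- match.arg(graph)
  merge <- match.arg(merge)
  norm_mode <- match.arg(norm_mode)
  if (d_model %% n_heads != 0L) stop("n_heads must divide d_model")
  if (!fusion %in% c("tcafm", "concat", "add", "avg", "max"))
    stop("unknown fusion method: ", fusion)
  if (!all(sources %in% c("rs", "cl", "so")) || length(sources) < 1L)
    stop("sources must be a nonempty subset of rs, cl, so")
  structure(list(
    d_model = as.integer(d_model), d_attn = as.integer(d_attn),
    n_heads = as.integer(n_heads), window = as.integer(window),
    stride = as.integer(stride), gru_layers = as.integer(gru_layers),
    gru_hidden = as.integer(gru_hidden), crb_blocks = as.integer(crb_blocks),
    crb_kernel = as.integer(crb_kernel), ffn_dim = as.integer(ffn_dim),
    fan_dp = as.integer(fan_dp), fan_dpbar = as.integer(fan_dpbar),
    graph = graph, graph_radius = as.integer(graph_radius), merge = merge,
    encoder_layers = as.integer(encoder_layers), dropout = dropout,
    use_tfe = isTRUE(use_tfe), use_gat = isTRUE(use_gat), fusion = fusion,
    sources = sources, norm_mode = norm_mode), class = "wf_model_config")
}

#' Sinusoidal positional encoding
#'
#' Standard Transformer encoding: `PE[t, 2i] = sin(t / 10000^(2i/d))`,
#' `PE[t, 2i+1] = cos(.)`, positions starting at 0.
#'
#' @param T_ number of positions; @param d encoding dimension.
#' @return `T_ x d` matrix.
#' @export
positional_encoding <- function(T_, d) {
  pos <- seq_len(T_) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2) * 2 / d))
  pe <- matrix(0, T_, d)
  even <- i %% 2 == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

#' Token-graph adjacency
#'
#' Symmetric 0/1 adjacency with self-loops: either fully connected or a
#' sliding neighborhood of the given radius (local feature aggregation).
#'
#' @param T_ token count; @param rule `"window_k"` or `"full"`;
#' @param radius neighborhood radius for `"window_k"`.
#' @return `T_ x T_` 0/1 matrix.
#' @export
token_adjacency <- function(T_, rule = "window_k", radius = 2L) {
  if (rule == "full") return(matrix(1, T_, T_))
  d <- abs(outer(seq_len(T_), seq_len(T_), "-"))
  (d <= radius) * 1
}

## ---- internal batched layers ------------------------------------------

# Multi-head self-attention over (B*T) x d tokens.
.mhsa <- function(ctx, x, T_, name, n_heads) {
  d <- ncol(ag_val(x))
  dh <- d %/% n_heads
  Q <- nn_linear(ctx, x, paste0(name, ".q"), d)
  K <- nn_linear(ctx, x, paste0(name, ".k"), d)
  V <- nn_linear(ctx, x, paste0(name, ".v"), d)
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ag_cols(Q, cols); kh <- ag_cols(K, cols); vh <- ag_cols(V, cols)
    sc <- ag_scale(ag_bmm(qh, kh, T_, transpose_y = TRUE), 1 / sqrt(dh))
    ag_bmm(ag_row_softmax(sc), vh, T_)
  })
  nn_linear(ctx, ag_cbind(heads), paste0(name, ".o"), d)
}

# Single-layer graph attention over (B*T) x d tokens with a fixed
# adjacency: additive pairwise scores, leaky-ReLU, neighborhood-masked
# softmax, aggregation of the value projections.
.gat <- function(ctx, x, T_, adj, name) {
  d <- ncol(ag_val(x))
  B <- nrow(ag_val(x)) / T_
  H <- nn_linear(ctx, x, paste0(name, ".v"), d)
  s_src <- nn_linear(ctx, H, paste0(name, ".a1"), 1L, bias = FALSE)
  s_dst <- nn_linear(ctx, H, paste0(name, ".a2"), 1L, bias = FALSE)
  ones <- ag_const(ctx$tape, matrix(1, B * T_, 1L))
  e <- ag_add(ag_bmm(s_src, ones, T_, transpose_y = TRUE),
              ag_bmm(ones, s_dst, T_, transpose_y = TRUE))
  e <- ag_leaky_relu(e, 0.2)
  mask <- matrix(rep(t(ifelse(adj > 0, 0, -1e9)), B), ncol = T_, byrow = TRUE)
  alpha <- ag_row_softmax(ag_addc(e, mask))
  ag_bmm(alpha, H, T_)
}

# One dual-branch encoder layer:
#   b1 = MHSA(x); b2 = GAT(x); merged per config; x = LN(x + merged)
#   f = FFN(x); x = LN(x + f)
.encoder_layer <- function(ctx, x, T_, mcfg, adj, name) {
  d <- mcfg$d_model
  b1 <- .mhsa(ctx, x, T_, paste0(name, ".mhsa"), mcfg$n_heads)
  merged <- if (mcfg$use_gat) {
    b2 <- .gat(ctx, x, T_, adj, paste0(name, ".gat"))
    if (mcfg$merge == "sum") ag_add(b1, b2)
    else nn_linear(ctx, ag_cbind(list(b1, b2)), paste0(name, ".merge"), d)
  } else b1
  x <- nn_layernorm(ctx, ag_add(x, merged), paste0(name, ".ln1"))
  f <- nn_linear(ctx, ag_gelu(nn_linear(ctx, x, paste0(name, ".ffn1"),
                                        mcfg$ffn_dim)),
                 paste0(name, ".ffn2"), d)
  nn_layernorm(ctx, ag_add(x, f), paste0(name, ".ln2"))
}

.encoder <- function(ctx, x, T_, mcfg) {
  adj <- token_adjacency(T_, mcfg$graph, mcfg$graph_radius)
  for (l in seq_len(mcfg$encoder_layers)) {
    x <- .encoder_layer(ctx, x, T_, mcfg, adj, paste0("enc.l", l))
  }
  x
}

# FAN layer: [cos(Wp x) || sin(Wp x) || act(Bbar + Wbar x)]
.fan_layer <- function(ctx, x, name, d_p, d_pbar) {
  p <- nn_linear(ctx, x, paste0(name, ".p"), d_p, bias = FALSE)
  np <- ag_gelu(nn_linear(ctx, x, paste0(name, ".np"), d_pbar))
  ag_cbind(list(ag_cos(p), ag_sin(p), np))
}

.decoder <- function(ctx, x, mcfg) {
  x <- .fan_layer(ctx, x, "fan.l1", mcfg$fan_dp, mcfg$fan_dpbar)
  x <- .fan_layer(ctx, x, "fan.l2", mcfg$fan_dp, mcfg$fan_dpbar)
  nn_linear(ctx, x, "head", 1L)
}

# Covariate tokens + input projection + positional encoding.
.assemble <- function(ctx, fused, batch, mcfg) {
  d <- mcfg$d_model
  x <- fused$node
  if (ncol(ag_val(x)) != d) x <- nn_linear(ctx, x, "in_proj", d)
  t_tok <- nn_linear(ctx, ag_const(ctx$tape, batch$time), "cov.time", d)
  r_tok <- nn_linear(ctx, ag_const(ctx$tape, batch$region), "cov.region", d)
  a_tok <- nn_linear(ctx, ag_const(ctx$tape, batch$area), "cov.area", d)
  seqs <- .token_concat(list(
    list(node = t_tok, T = 1L), list(node = r_tok, T = 1L),
    list(node = a_tok, T = 1L), list(node = x, T = fused$T)))
  T_ <- seqs$T
  pe <- positional_encoding(T_, d)
  list(node = ag_addc(seqs$node, pe[rep(seq_len(T_), batch$B), , drop = FALSE]),
       T = T_)
}

# Full forward pass: batch -> normalized yield predictions (B x 1 node).
.forward <- function(ctx, batch, mcfg) {
  embs <- .extract_all(ctx, batch, mcfg)
  fused <- .fuse(ctx, embs, mcfg)
  asm <- .assemble(ctx, fused, batch, mcfg)
  enc <- .encoder(ctx, asm$node, asm$T, mcfg)
  pooled <- ag_group_mean_rows(enc, asm$T)
  .decoder(ctx, pooled, mcfg)
}

## ---- model object ------------------------------------------------------

# Slice a precomputed full-dataset batch (from make_batch over all
# records) down to the given record indices. Avoids re-normalizing every
# record at every training step.
slice_batch <- function(cache, idx) {
  L <- cache$L
  rows <- rep((idx - 1L) * L, each = L) + seq_len(L)
  sub <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  list(B = length(idx), L = L,
       rs = cache$rs[rows, , drop = FALSE], rs_stats = sub(cache$rs_stats),
       cl = cache$cl[rows, , drop = FALSE], cl_stats = sub(cache$cl_stats),
       sod = cache$sod[rows, , drop = FALSE], sod_stats = sub(cache$sod_stats),
       static = sub(cache$static), time = sub(cache$time),
       region = sub(cache$region), area = sub(cache$area),
       y = sub(cache$y))
}

# Assemble stacked input matrices for a list of records.
make_batch <- function(model, records) {
  ns <- model$normalizer
  mcfg <- model$config
  B <- length(records)
  L <- nrow(records[[1]]$rs)
  dyn <- function(source, field) {
    res <- lapply(records, function(r) normalize_series(ns, r[[field]], source))
    list(x = do.call(rbind, lapply(res, `[[`, "x")),
         stats = if (ns$mode == "instance")
           do.call(rbind, lapply(res, `[[`, "stats")) else NULL)
  }
  rs <- dyn("rs", "rs"); cl <- dyn("climate", "climate")
  sod <- dyn("soil_dyn", "soil_dyn")
  static <- do.call(rbind, lapply(records, function(r)
    (r$soil_static - ns$static_mean) / ns$static_sd))
  cov <- lapply(records, encode_covariates, ns = ns,
                n_regions = model$n_regions)
  y <- vapply(records, `[[`, 0, "yield")
  list(B = B, L = L,
       rs = rs$x, rs_stats = rs$stats,
       cl = cl$x, cl_stats = cl$stats,
       sod = sod$x, sod_stats = sod$stats,
       static = static,
       time = matrix(vapply(cov, `[[`, 0, "time"), ncol = 1),
       region = do.call(rbind, lapply(cov, `[[`, "region")),
       area = matrix(vapply(cov, `[[`, 0, "area"), ncol = 1),
       y = matrix((y - ns$yield_mean) / ns$yield_sd, ncol = 1))
}

#' Construct a yield prediction model
#'
#' Fits the normalizer on the training records and initializes all
#' parameters deterministically from `seed` by tracing one forward pass.
#'
#' @param config a [model_config()].
#' @param dataset a `wf_dataset` (complete records, no NA).
#' @param split a `wf_split`; normalization statistics use `split$train`
#'   only, so test labels never leak into preprocessing.
#' @param n_regions number of region codes (defaults to the dataset
#'   config, or the max observed id + 1).
#' @param seed parameter initialization seed.
#' @return object of class `wf_model`.
#' @export
wf_model <- function(config, dataset, split, n_regions = NULL, seed = 1L) {
  records <- dataset$records
  if (is.null(n_regions)) {
    n_regions <- if (!is.null(dataset$config)) dataset$config$n_regions
      else max(vapply(records, `[[`, 0L, "region_id")) + 1L
  }
  ns <- fit_normalizer(records[split$train], mode = config$norm_mode)
  model <- structure(list(config = config, normalizer = ns,
                          n_regions = as.integer(n_regions),
                          store = wf_store(), seed = as.integer(seed)),
                     class = "wf_model")
  # trace one batch in init mode to create every parameter
  tmpl <- records[split$train[seq_len(min(2L, length(split$train)))]]
  batch <- make_batch(model, tmpl)
  ctx <- nn_ctx(model$store, training = FALSE, init = TRUE)
  with_seed(seed, .forward(ctx, batch, config))
  model
}

#' @export
print.wf_model <- function(x, ...) {
  n_par <- sum(vapply(as.list(x$store), length, 0L))
  cat(sprintf(
    "<wf_model> d_model %d, %d sources, fusion %s, %d parameters\n",
    x$config$d_model, length(x$config$sources), x$config$fusion, n_par))
  invisible(x)
}

#' Predict yields for season records
#'
#' Runs the full pipeline (per-source extraction, fusion, covariate
#' assembly, dual-branch encoder, FAN decoder) in evaluation mode and
#' de-normalizes to kg/hm^2.
#'
#' @param object a `wf_model`.
#' @param records list of complete `season_record`s (or a `wf_dataset`).
#' @param batch_size records per forward pass.
#' @param ... unused.
#' @return numeric vector of predicted yields (kg/hm^2).
#' @export
predict.wf_model <- function(object, records, batch_size = 64L, ...) {
  if (inherits(records, "wf_dataset")) records <- records$records
  if (inherits(records, "season_record")) records <- list(records)
  cache <- make_batch(object, records)
  out <- numeric(0)
  for (i in seq(1L, length(records), by = batch_size)) {
    idx <- i:min(i + batch_size - 1L, length(records))
    batch <- slice_batch(cache, idx)
    ctx <- nn_ctx(object$store, training = FALSE, init = FALSE)
    yhat <- ag_val(.forward(ctx, batch, object$config))
    if (!all(is.finite(yhat))) stop("non-finite prediction from decoder")
    out <- c(out, normalizer_invert(object$normalizer, as.numeric(yhat)))
  }
  out
}

## ---- exported layer-level wrappers ------------------------------------

#' Graph attention over a token sequence
#'
#' @param tokens `T x d` matrix.
#' @param adjacency symmetric 0/1 `T x T` matrix with self-loops.
#' @inheritParams crb_forward
#' @return `T x d` matrix.
#' @export
graph_attention <- function(tokens, adjacency, store = wf_store(),
                            name = "gat", init_seed = 0L) {
  T_ <- nrow(tokens)
  stopifnot(nrow(adjacency) == T_, ncol(adjacency) == T_)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) == 0)) stop("adjacency must include self-loops")
  .run_op(store, init_seed, function(ctx)
    .gat(ctx, ag_const(ctx$tape, tokens), T_, adjacency, name))
}

#' Dual-branch encoder forward pass
#'
#' @param tokens `T x d_model` matrix.
#' @param config a [model_config()].
#' @inheritParams crb_forward
#' @return `T x d_model` matrix.
#' @export
encoder_forward <- function(tokens, config = model_config(),
                            store = wf_store(), init_seed = 0L) {
  stopifnot(is.matrix(tokens), all(is.finite(tokens)))
  .run_op(store, init_seed, function(ctx)
    .encoder(ctx, ag_const(ctx$tape, tokens), nrow(tokens), config))
}

#' Fourier analysis network layer forward pass
#'
#' Output is `[cos(Wp x) || sin(Wp x) || gelu(Bbar + Wbar x)]`, width
#' `2*d_p + d_pbar`; the periodic blocks embed seasonal/periodic structure
#' directly in the decoder.
#'
#' @param x input matrix (rows are samples).
#' @param d_p periodic width; @param d_pbar non-periodic width.
#' @inheritParams crb_forward
#' @return matrix with `2*d_p + d_pbar` columns.
#' @export
fan_forward <- function(x, d_p = 16L, d_pbar = 32L, store = wf_store(),
                        name = "fan", init_seed = 0L) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  .run_op(store, init_seed, function(ctx)
    .fan_layer(ctx, ag_const(ctx$tape, x), name, d_p, d_pbar))
}

#' Assemble encoder input for one record
#'
#' Prepends the three covariate tokens (time, region, area) to the fused
#' tokens and adds sinusoidal positional encodings.
#'
#' @param fused fused token matrix for one sample.
#' @param record the corresponding `season_record`.
#' @param model a `wf_model`.
#' @return `(tokens + 3) x d_model` matrix.
#' @export
assemble_input <- function(fused, record, model) {
  batch <- make_batch(model, list(record))
  ctx <- nn_ctx(model$store, training = FALSE, init = TRUE)
  asm <- .assemble(ctx, list(node = ag_const(ctx$tape, fused),
                             T = nrow(fused)), batch, model$config)
  ag_val(asm$node)
}
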
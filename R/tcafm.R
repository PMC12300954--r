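# Triple cross-attention fusion.
#
# The three source embeddings (remote sensing, climate, soil) interact
# through the six ordered cross-attention pairs (Q from one source, K from
# the other), implemented with linear-complexity efficient additive
# attention: per-token scores against a learned query vector, a softmax
# over tokens, a global query formed as the softmax-weighted sum, and a
# gated combination with the other source's keys. The six outputs are
# concatenated along the channel axis, passed through a CRB, and gated by
# sigmoid(MLP) followed by layer normalization.

#' The six ordered cross-attention pairs
#'
#' @return data.frame with columns `query`, `key`: both directions of each
#'   unordered pair over \{rs, cl, so\}.
#' @export
cross_pairs <- function() {
  src <- c("rs", "cl", "so")
  g <- expand.grid(query = src, key = src, stringsAsFactors = FALSE)
  g <- g[g$query != g$key, ]
  g <- g[order(match(g$query, src), match(g$key, src)), ]
  rownames(g) <- NULL
  g
}

# Q/K projections for one embedding under one pair's parameter set.
.project_qk <- function(ctx, emb, name, d_attn) {
  list(Q = nn_linear(ctx, emb, paste0(name, ".q"), d_attn),
       K = nn_linear(ctx, emb, paste0(name, ".k"), d_attn))
}

# Efficient additive attention: Q, K are (B*T) x d sample-major.
#   a_i = (Q_i . w) / sqrt(d);  alpha = softmax_tokens(a)
#   g = sum_i alpha_i Q_i  (global query, per sample)
#   out_i = layernorm(Q_i + Linear(g * K_i))
.eaa <- function(ctx, Q, K, T_, name) {
  d <- ncol(ag_val(Q))
  w <- nn_param(ctx, paste0(name, ".w"), d, 1L)
  a <- ag_scale(ag_matmul(Q, w), 1 / sqrt(d))
  alpha <- ag_group_softmax(a, T_)
  gq <- ag_group_weighted_sum(alpha, Q, T_)
  gk <- ag_mul(ag_repeat_rows(gq, T_), K)
  ag_layernorm(ag_add(Q, nn_linear(ctx, gk, paste0(name, ".out"), d)))
}

# Linearly resample a token sequence from T_in to T_out tokens
# (convex combination of the two nearest source tokens).
.align_tokens <- function(emb, T_out) {
  T_in <- emb$T
  if (T_in == T_out) return(emb)
  x <- emb$node
  B <- nrow(ag_val(x)) / T_in
  pos <- if (T_out == 1L) 1 else 1 + (seq_len(T_out) - 1) * (T_in - 1) / (T_out - 1)
  lo <- pmin(floor(pos), T_in)
  hi <- pmin(lo + 1, T_in)
  wt <- pos - lo
  base <- rep((seq_len(B) - 1L) * T_in, each = T_out)
  xlo <- ag_gather_rows(x, base + rep(as.integer(lo), B))
  xhi <- ag_gather_rows(x, base + rep(as.integer(hi), B))
  D <- ncol(ag_val(x))
  W <- matrix(rep(wt, B), ncol = 1)[, rep(1, D), drop = FALSE]
  list(node = ag_add(ag_mulc(xlo, 1 - W), ag_mulc(xhi, W)), T = T_out)
}

# TCAFM fusion over the three embeddings; returns list(node, T).
.tcafm <- function(ctx, embs, mcfg) {
  d_attn <- mcfg$d_attn
  T_common <- max(vapply(embs, `[[`, 0L, "T"))
  aligned <- lapply(embs, .align_tokens, T_out = T_common)
  pairs <- cross_pairs()
  outs <- lapply(seq_len(nrow(pairs)), function(i) {
    qs <- pairs$query[i]; ks <- pairs$key[i]
    pname <- paste0("tcafm.", qs, "_", ks)
    Q <- nn_linear(ctx, aligned[[qs]]$node, paste0(pname, ".q"), d_attn)
    K <- nn_linear(ctx, aligned[[ks]]$node, paste0(pname, ".k"), d_attn)
    .eaa(ctx, Q, K, T_common, paste0(pname, ".attn"))
  })
  x <- ag_cbind(outs) # channel concat: 6 * d_attn
  x <- .crb(ctx, x, T_common,
            crb_spec(6L * d_attn, mcfg$d_model, mcfg$crb_kernel,
                     mcfg$crb_blocks), "tcafm.crb")
  # gate of the fused features:
  # layernorm(sigmoid(linear(relu(dropout(linear(x)))))), applied
  # multiplicatively to x
  gmask <- NULL
  g <- nn_linear(ctx, x, "tcafm.gate.fc1", mcfg$d_model)
  g <- ag_dropout(g, mcfg$dropout, ctx$training)
  g <- ag_relu(g)
  g <- nn_linear(ctx, g, "tcafm.gate.fc2", mcfg$d_model)
  g <- ag_layernorm(ag_sigmoid(g))
  list(node = ag_mul(x, g), T = T_common)
}

# Baseline fusion used by the ablation grid: concat / add / avg / max over
# the aligned embeddings.
.fuse_baseline <- function(ctx, embs, mcfg, method) {
  T_common <- max(vapply(embs, `[[`, 0L, "T"))
  aligned <- lapply(embs, .align_tokens, T_out = T_common)
  nodes <- lapply(aligned, `[[`, "node")
  node <- switch(method,
    concat = ag_cbind(nodes),
    add = Reduce(ag_add, nodes),
    avg = ag_scale(Reduce(ag_add, nodes), 1 / length(nodes)),
    max = Reduce(ag_max2, nodes),
    stop("unknown fusion method: ", method))
  list(node = node, T = T_common)
}

.fuse <- function(ctx, embs, mcfg) {
  if (length(embs) == 1L) return(embs[[1]])
  if (mcfg$fusion == "tcafm") .tcafm(ctx, embs, mcfg)
  else .fuse_baseline(ctx, embs, mcfg, mcfg$fusion)
}

## ---- exported single-sample wrappers ----------------------------------

#' Q/K projections of an embedding
#'
#' Two learned linear maps of a token embedding, as used by the fusion
#' attention (one parameter set per ordered source pair).
#'
#' @param embedding token matrix `tokens x d_model`.
#' @param d_attn attention dimension.
#' @inheritParams crb_forward
#' @return list with matrices `Q` and `K` (`tokens x d_attn`).
#' @export
project_qk <- function(embedding, d_attn = ncol(embedding),
                       store = wf_store(), name = "pair", init_seed = 0L) {
  stopifnot(is.matrix(embedding), all(is.finite(embedding)))
  ctx <- nn_ctx(store, training = FALSE, init = TRUE)
  res <- with_seed(init_seed, {
    e <- ag_const(ctx$tape, embedding)
    list(Q = nn_linear(ctx, e, paste0(name, ".q"), d_attn),
         K = nn_linear(ctx, e, paste0(name, ".k"), d_attn))
  })
  lapply(res, ag_val)
}

#' Efficient additive attention forward pass
#'
#' Linear-complexity attention: per-token scores `a_i = Q_i . w / sqrt(d)`
#' are softmax-normalized over tokens, the global query `g = sum_i alpha_i
#' Q_i` modulates the keys elementwise, and each output token is
#' `layernorm(Q_i + Linear(g * K_i))`.
#'
#' @param Q,K `tokens x d` matrices (same token count).
#' @inheritParams crb_forward
#' @return `tokens x d` matrix, with the softmax token weights attached as
#'   attribute `"alpha"`.
#' @export
efficient_additive_attention <- function(Q, K, store = wf_store(),
                                         name = "eaa", init_seed = 0L) {
  if (nrow(Q) != nrow(K) || ncol(Q) != ncol(K))
    stop("Q and K must have identical shape")
  out <- .run_op(store, init_seed, function(ctx)
    .eaa(ctx, ag_const(ctx$tape, Q), ag_const(ctx$tape, K), nrow(Q), name))
  a <- as.numeric(Q %*% store[[paste0(name, ".w")]]) / sqrt(ncol(Q))
  e <- exp(a - max(a))
  attr(out, "alpha") <- e / sum(e)
  out
}

#' Triple cross-attention fusion of three embeddings
#'
#' Computes the six ordered cross-attention interactions among the rs/cl/so
#' embeddings (token counts aligned by linear resampling), concatenates
#' them along the channel axis, applies a CRB, and multiplies by the
#' sigmoid/layer-norm gate.
#'
#' @param rs,cl,so token matrices sharing the model dimension.
#' @param config a [model_config()] supplying `d_attn`, CRB and dropout
#'   settings.
#' @inheritParams crb_forward
#' @return fused token matrix `tokens x d_model`.
#' @export
tcafm_fuse <- function(rs, cl, so, config = model_config(),
                       store = wf_store(), init_seed = 0L) {
  for (m in list(rs, cl, so)) {
    if (!is.matrix(m) || !all(is.finite(m))) stop("embeddings must be finite matrices")
  }
  if (length(unique(c(ncol(rs), ncol(cl), ncol(so)))) != 1L)
    stop("embeddings must share d_model")
  .run_op(store, init_seed, function(ctx) {
    embs <- list(rs = list(node = ag_const(ctx$tape, rs), T = nrow(rs)),
                 cl = list(node = ag_const(ctx$tape, cl), T = nrow(cl)),
                 so = list(node = ag_const(ctx$tape, so), T = nrow(so)))
    .tcafm(ctx, embs, config)$node
  })
}
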
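# Layer library: parameter store, linear / layer-norm / GRU / 1-D conv
# building blocks, and the Adam optimizer. Parameters live in an environment
# keyed by hierarchical names ("tfe_rs.gru1.W_xz", ...). Shapes are fixed on
# the first (init-mode) forward pass, which makes initialization a
# deterministic function of the model seed and the forward graph.

# Evaluate `code` under a temporary RNG state so library calls never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Forward-pass context: tape + parameter store + per-tape node cache.
nn_ctx <- function(store, training = FALSE, init = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- ag_tape()
  ctx$store <- store     # environment: name -> matrix
  ctx$cache <- new.env(parent = emptyenv())
  ctx$training <- training
  ctx$init <- init
  ctx
}

nn_glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

nn_param <- function(ctx, name, nr, nc, init = "glorot") {
  if (is.null(ctx$store[[name]])) {
    if (!isTRUE(ctx$init)) stop("unknown parameter: ", name)
    ctx$store[[name]] <- switch(init,
      glorot = nn_glorot(nr, nc),
      zeros  = matrix(0, nr, nc),
      ones   = matrix(1, nr, nc),
      stop("unknown init: ", init))
  }
  nd <- ctx$cache[[name]]
  if (is.null(nd)) {
    nd <- ag_param(ctx$tape, ctx$store[[name]], name)
    ctx$cache[[name]] <- nd
  }
  nd
}

nn_linear <- function(ctx, x, name, d_out, bias = TRUE) {
  d_in <- ncol(ag_val(x))
  W <- nn_param(ctx, paste0(name, ".W"), d_in, d_out)
  b <- if (bias) nn_param(ctx, paste0(name, ".b"), 1L, d_out, init = "zeros")
  ag_linear(x, W, b)
}

nn_layernorm <- function(ctx, x, name, eps = 1e-5) {
  d <- ncol(ag_val(x))
  g <- nn_param(ctx, paste0(name, ".gamma"), 1L, d, init = "ones")
  b <- nn_param(ctx, paste0(name, ".beta"), 1L, d, init = "zeros")
  ag_layernorm_affine(x, g, b, eps)
}

## ---- GRU ---------------------------------------------------------------

# One GRU step (fused node). Parameters <name>.Wx, <name>.Wh, <name>.bx,
# <name>.bh with gate columns [r | z | n]; see ag_gru_step for the update.
nn_gru_step <- function(ctx, x, h, name, d_h) {
  d_in <- ncol(ag_val(x))
  ag_gru_step(x, h,
              nn_param(ctx, paste0(name, ".Wx"), d_in, 3L * d_h),
              nn_param(ctx, paste0(name, ".Wh"), d_h, 3L * d_h),
              nn_param(ctx, paste0(name, ".bx"), 1L, 3L * d_h, init = "zeros"),
              nn_param(ctx, paste0(name, ".bh"), 1L, 3L * d_h, init = "zeros"))
}

# Stacked GRU over a short sequence given as a list of step inputs
# (each n x d_in). Returns the final hidden state of the top layer (n x d_h).
nn_gru_stack <- function(ctx, steps, name, n_layers, d_h) {
  n <- nrow(ag_val(steps[[1]]))
  for (l in seq_len(n_layers)) {
    h <- ag_const(ctx$tape, matrix(0, n, d_h))
    outs <- vector("list", length(steps))
    for (s in seq_along(steps)) {
      h <- nn_gru_step(ctx, steps[[s]], h, paste0(name, ".l", l), d_h)
      outs[[s]] <- h
    }
    steps <- outs # layer l's outputs feed layer l+1
  }
  steps[[length(steps)]]
}

## ---- 1-D convolution over token sequences ------------------------------

# Row-shift index for sample blocks: row t of each block reads row t+offset,
# 0 (= zero row) outside [1, T]. Cached per (B, T, offset).
.shift_cache <- new.env(parent = emptyenv())
shift_idx <- function(B, T_, offset) {
  key <- paste(B, T_, offset, sep = "_")
  idx <- .shift_cache[[key]]
  if (is.null(idx)) {
    t_ <- seq_len(T_) + offset
    t_[t_ < 1L | t_ > T_] <- NA_integer_
    base <- rep((seq_len(B) - 1L) * T_, each = T_)
    idx <- base + rep(t_, B)
    idx[is.na(idx)] <- 0L
    .shift_cache[[key]] <- idx
  }
  idx
}

# Same-padded conv over the token axis: x is (B*T) x C_in sample-major,
# kernel width k (odd). Implemented as a gather of the k shifted token
# views, channel concatenation, and one dense matmul.
nn_conv1d <- function(ctx, x, name, T_, k, d_out) {
  if (k %% 2L == 0L) stop("conv kernel must be odd (same padding undefined)")
  nn_linear(ctx, if (k == 1L) x else ag_unfold(x, T_, k), name, d_out)
}

## ---- optimizer ---------------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- list(); st$v <- list()
  st
}

adam_step <- function(st, store, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    st$m[[nm]] <- m; st$v[[nm]] <- v
    store[[nm]] <- store[[nm]] - st$lr * (m / c1) / (sqrt(v / c2) + st$eps)
  }
  invisible(st)
}

# Deep copy of a parameter store (used for best-checkpoint restore).
store_snapshot <- function(store) as.list(store)
store_restore <- function(store, snap) {
  for (nm in names(snap)) store[[nm]] <- snap[[nm]]
  invisible(store)
}
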
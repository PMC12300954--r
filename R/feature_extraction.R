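# Per-source deep feature extraction.
#
# Dynamic sources (remote sensing, climate, dynamic soil) go through a
# temporal feature extractor (TFE): sliding windows over the months, a
# stack of GRUs run over each window, and a convolutional residual block
# (CRB) over the resulting window tokens. The static soil vector goes
# through a linear lift and a kernel-1 CRB, contributing one extra token
# that is concatenated onto the dynamic-soil tokens. All sources emit
# embeddings with a common model dimension so the fusion stage can attend
# across them.
#
# Parameter naming: every learnable tensor lives in a flat store under
# hierarchical names, e.g. "tfe_rs.gru.l1.xr.W", "tfe_rs.crb.b1.conv1.W",
# "crb_sos.b1.conv2.b". Tests can pre-seed a store with known weights.

#' Convolutional residual block specification
#'
#' @param channels_in,channels_out positive channel counts; when they
#'   differ the skip path uses an explicit 1x1 projection.
#' @param kernel odd positive kernel width (same padding).
#' @param n_blocks number of stacked residual blocks.
#' @return object of class `crb_spec`.
#' @export
crb_spec <- function(channels_in, channels_out = channels_in, kernel = 3L,
                     n_blocks = 2L) {
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("kernel must be an odd positive integer (same padding)")
  if (channels_in < 1L || channels_out < 1L || n_blocks < 1L)
    stop("channels and n_blocks must be positive")
  structure(list(channels_in = as.integer(channels_in),
                 channels_out = as.integer(channels_out),
                 kernel = as.integer(kernel),
                 n_blocks = as.integer(n_blocks)), class = "crb_spec")
}

#' Temporal feature extractor specification
#'
#' @param window sliding-window length over months.
#' @param stride window stride.
#' @param gru_layers number of stacked GRU layers (>= 2).
#' @param hidden GRU hidden width.
#' @param crb a [crb_spec()] applied over the window tokens.
#' @return object of class `tfe_spec`.
#' @export
tfe_spec <- function(window = 3L, stride = 1L, gru_layers = 2L, hidden = 64L,
                     crb = crb_spec(hidden, hidden)) {
  if (window < 1L || stride < 1L) stop("window and stride must be positive")
  if (gru_layers < 2L) stop("gru_layers must be >= 2 (GRUs in series)")
  if (hidden < 1L) stop("hidden must be positive")
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 gru_layers = as.integer(gru_layers),
                 hidden = as.integer(hidden), crb = crb), class = "tfe_spec")
}

#' Number of sliding-window tokens
#'
#' `floor((L - window) / stride) + 1` for a series of length `L`.
#'
#' @param L series length; @param window,stride window parameters.
#' @return token count (>= 1; errors if window > L).
#' @export
n_windows <- function(L, window, stride) {
  if (window > L) stop("window exceeds series length")
  as.integer((L - window) %/% stride + 1L)
}

## ---- internal batched forwards ----------------------------------------

# CRB over token sequences: x is (B*T) x C_in sample-major.
# Each block: conv -> layernorm -> GELU -> conv, plus (projected) skip.
.crb <- function(ctx, x, T_, spec, name) {
  c_out <- spec$channels_out
  for (b in seq_len(spec$n_blocks)) {
    pre <- paste0(name, ".b", b)
    y <- nn_conv1d(ctx, x, paste0(pre, ".conv1"), T_, spec$kernel, c_out)
    y <- nn_layernorm(ctx, y, paste0(pre, ".ln"))
    y <- ag_gelu(y)
    y <- nn_conv1d(ctx, y, paste0(pre, ".conv2"), T_, spec$kernel, c_out)
    skip <- if (ncol(ag_val(x)) == c_out) x else
      nn_linear(ctx, x, paste0(pre, ".proj"), c_out, bias = FALSE)
    x <- ag_add(y, skip)
  }
  x
}

# TFE: series (B*L) x V sample-major -> (B*nw) x d tokens.
.tfe <- function(ctx, x, B, L, spec, name) {
  w <- spec$window; s <- spec$stride
  nw <- n_windows(L, w, s)
  steps <- lapply(seq_len(w), function(st) {
    # row index of month (j-1)*s + st for window j of each sample
    m <- (seq_len(nw) - 1L) * s + st
    idx <- rep((seq_len(B) - 1L) * L, each = nw) + rep(m, B)
    ag_gather_rows(x, idx)
  })
  h <- nn_gru_stack(ctx, steps, paste0(name, ".gru"), spec$gru_layers,
                    spec$hidden)
  .crb(ctx, h, nw, spec$crb, paste0(name, ".crb"))
}

# Concatenate token sequences along the token axis, sample-major.
# pieces: list of list(node, T); returns list(node, T).
.token_concat <- function(pieces) {
  big <- ag_rbind(lapply(pieces, `[[`, "node"))
  Ts <- vapply(pieces, `[[`, 0L, "T")
  B <- nrow(ag_val(pieces[[1]]$node)) / Ts[1]
  offs <- c(0L, cumsum(Ts * B))[seq_along(Ts)]
  idx <- unlist(lapply(seq_len(B), function(b) {
    unlist(lapply(seq_along(pieces), function(p) {
      offs[p] + (b - 1L) * Ts[p] + seq_len(Ts[p])
    }))
  }))
  list(node = ag_gather_rows(big, idx), T = sum(Ts))
}

# Per-source embeddings for a batch. Returns list of embeddings
# (each list(node, T)) for the sources requested by the model config.
.extract_all <- function(ctx, batch, mcfg) {
  B <- batch$B; L <- batch$L
  d <- mcfg$d_model
  emb_dynamic <- function(xname, tag) {
    # ctx$want_input_grads registers inputs as leaves so d(yhat)/d(input)
    # can be read off the tape (gradient diagnostics and tests)
    x <- if (isTRUE(ctx$want_input_grads)) {
      ag_param(ctx$tape, batch[[xname]], paste0("input.", xname))
    } else ag_const(ctx$tape, batch[[xname]])
    if (mcfg$use_tfe) {
      spec <- tfe_spec(window = min(mcfg$window, L), stride = mcfg$stride,
                       gru_layers = mcfg$gru_layers, hidden = mcfg$gru_hidden,
                       crb = crb_spec(mcfg$gru_hidden, d, mcfg$crb_kernel,
                                      mcfg$crb_blocks))
      node <- .tfe(ctx, x, B, L, spec, paste0("tfe_", tag))
      T_ <- n_windows(L, min(mcfg$window, L), mcfg$stride)
    } else {
      # ablation: no TFE, each month is lifted to d_model directly
      node <- nn_linear(ctx, x, paste0("lift_", tag), d)
      T_ <- L
    }
    # reversible-instance-normalization statistics re-injected as a
    # broadcast-added embedding, so the per-sample level/scale survives
    stats_name <- paste0(xname, "_stats")
    if (!is.null(batch[[stats_name]])) {
      sn <- nn_linear(ctx, ag_const(ctx$tape, batch[[stats_name]]),
                      paste0("stats_", tag), d)
      node <- ag_add(node, ag_repeat_rows(sn, T_))
    }
    list(node = node, T = T_)
  }
  out <- list()
  if ("rs" %in% mcfg$sources) out$rs <- emb_dynamic("rs", "rs")
  if ("cl" %in% mcfg$sources) out$cl <- emb_dynamic("cl", "cl")
  if ("so" %in% mcfg$sources) {
    sod <- emb_dynamic("sod", "sod")
    sos <- nn_linear(ctx, ag_const(ctx$tape, batch$static), "lift_sos", d)
    sos <- .crb(ctx, sos, 1L,
                crb_spec(d, d, kernel = 1L, n_blocks = mcfg$crb_blocks),
                "crb_sos")
    out$so <- .token_concat(list(sod, list(node = sos, T = 1L)))
  }
  out
}

## ---- exported single-record wrappers ----------------------------------

#' Parameter store
#'
#' A flat environment mapping hierarchical parameter names to matrices.
#' Missing parameters encountered by a forward pass are initialized
#' (Glorot uniform) under `init_seed`, so repeated calls are deterministic.
#'
#' @return an empty environment to pass as `store`.
#' @export
wf_store <- function() new.env(parent = emptyenv())

.run_op <- function(store, init_seed, fn) {
  ctx <- nn_ctx(store, training = FALSE, init = TRUE)
  node <- with_seed(init_seed, fn(ctx))
  ag_val(node)
}

#' Convolutional residual block forward pass
#'
#' Input is a token sequence (`length x channels`); each block applies
#' conv -> layer norm -> GELU -> conv with a residual skip (1x1-projected
#' when channel counts differ). The token length is preserved.
#'
#' @param x numeric matrix, `length x channels_in`.
#' @param spec a [crb_spec()].
#' @param store parameter store from [wf_store()] (filled on first use).
#' @param name parameter name prefix.
#' @param init_seed seed for lazily initialized parameters.
#' @return numeric matrix `length x channels_out`.
#' @export
crb_forward <- function(x, spec, store = wf_store(), name = "crb",
                        init_seed = 0L) {
  stopifnot(is.matrix(x), all(is.finite(x)), ncol(x) == spec$channels_in)
  .run_op(store, init_seed, function(ctx)
    .crb(ctx, ag_const(ctx$tape, x), nrow(x), spec, name))
}

#' Temporal feature extractor forward pass
#'
#' Slices the monthly series into sliding windows, runs the stacked GRUs
#' over each window (the final hidden state of the top layer is the
#' window's token), and applies a CRB over the token sequence.
#'
#' @param series numeric matrix `months x vars` (complete, no NA).
#' @param spec a [tfe_spec()].
#' @inheritParams crb_forward
#' @return token matrix `n_windows x channels_out`.
#' @export
tfe_forward <- function(series, spec, store = wf_store(), name = "tfe",
                        init_seed = 0L) {
  if (!all(is.finite(series))) stop("series contains non-finite values")
  L <- nrow(series)
  if (spec$window > L) stop("window exceeds series length")
  .run_op(store, init_seed, function(ctx)
    .tfe(ctx, ag_const(ctx$tape, series), 1L, L, spec, name))
}

#' Per-source embeddings for one record
#'
#' Runs the three per-source extractors of a model on a single season
#' record and returns the aligned embeddings (all with the model
#' dimension as last axis).
#'
#' @param record a complete `season_record`.
#' @param model a `wf_model` (see [wf_model()]).
#' @return named list of token matrices `rs`, `cl`, `so`.
#' @export
extract_all <- function(record, model) {
  batch <- make_batch(model, list(record))
  ctx <- nn_ctx(model$store, training = FALSE, init = FALSE)
  embs <- .extract_all(ctx, batch, model$config)
  out <- lapply(embs, function(e) ag_val(e$node))
  for (nm in names(out)) {
    if (!all(is.finite(out[[nm]]))) stop("non-finite embedding for ", nm)
  }
  out
}
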
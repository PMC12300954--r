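# TFE and CRB forward contracts: token counts, zero-weight traces, a
# direct-convolution oracle, embedding alignment, and gradient flow.

test_that("sliding-window token count follows the formula", {
  expect_equal(n_windows(9, 3, 1), 7L)
  expect_equal(n_windows(9, 9, 1), 1L)
  expect_error(n_windows(9, 10, 1), "window")
  # property: formula vs brute-force enumeration of window start positions
  for (L in c(4L, 7L, 9L)) {
    for (w in 1:L) {
      for (s in 1:3) {
        starts <- seq(1L, L - w + 1L, by = s)
        expect_equal(n_windows(L, w, s), length(starts))
      }
    }
  }
})

test_that("tfe_forward emits one token per window and is order-aware", {
  set.seed(31)
  series <- matrix(stats::rnorm(9 * 2), 9, 2)
  spec <- tfe_spec(window = 3L, stride = 1L, gru_layers = 2L, hidden = 6L,
                   crb = crb_spec(6L, 6L))
  store <- wf_store()
  out <- tfe_forward(series, spec, store, init_seed = 1L)
  expect_identical(dim(out), c(7L, 6L))
  expect_true(all(is.finite(out)))
  # purity: identical params + input give identical output
  expect_identical(tfe_forward(series, spec, store), out)
  # order sensitivity: permuting months changes the embedding
  perm <- series[c(2, 1, 4, 3, 6, 5, 8, 7, 9), ]
  expect_false(isTRUE(all.equal(tfe_forward(perm, spec, store), out)))
  # degenerate whole-season window
  spec9 <- tfe_spec(window = 9L, hidden = 6L, crb = crb_spec(6L, 6L))
  out9 <- tfe_forward(series, spec9, wf_store(), init_seed = 1L)
  expect_identical(nrow(out9), 1L)
  expect_error(tfe_forward(series, tfe_spec(window = 10L, hidden = 4L,
                                            crb = crb_spec(4L))),
               "window")
  series[3, 1] <- NA
  expect_error(tfe_forward(series, spec, store), "finite")
})

test_that("all-zero GRU and CRB weights give the zero tensor", {
  # hand trace: zero gates make r = z = 1/2, candidate n = 0, so the
  # hidden state stays 0; zero convolutions then map 0 to 0 (layer norm
  # of a constant row is beta = 0)
  set.seed(32)
  series <- matrix(stats::rnorm(18), 9, 2)
  spec <- tfe_spec(window = 3L, hidden = 5L, crb = crb_spec(5L, 5L))
  store <- wf_store()
  tfe_forward(series, spec, store, init_seed = 1L) # create params
  set_params(store, ".")
  set_params(store, "ln.gamma$", 1) # layer-norm scale back to 1
  out <- tfe_forward(series, spec, store)
  expect_equal(max(abs(out)), 0)
})

test_that("crb_forward: residual identity, zero propagation, length", {
  set.seed(33)
  x <- matrix(stats::rnorm(12), 4, 3)
  spec <- crb_spec(3L, 3L, kernel = 3L, n_blocks = 2L)
  store <- wf_store()
  out <- crb_forward(x, spec, store, init_seed = 2L)
  expect_identical(dim(out), dim(x))
  # zero conv weights + identity skip: output equals input
  set_params(store, "conv[12]\\.(W|b)$")
  expect_equal(crb_forward(x, spec, store), x)
  # zero input with zero biases stays zero
  store2 <- wf_store()
  crb_forward(x, spec, store2, init_seed = 2L)
  set_params(store2, "\\.b$")
  set_params(store2, "ln.beta$")
  expect_equal(max(abs(crb_forward(matrix(0, 4, 3), spec, store2))), 0)
  expect_error(crb_spec(3L, 3L, kernel = 2L), "odd")
})

test_that("a CRB block matches a direct convolution-by-loop oracle", {
  set.seed(34)
  Cin <- 2L; Cout <- 2L; L <- 5L; k <- 3L
  x <- matrix(stats::rnorm(L * Cin), L, Cin)
  spec <- crb_spec(Cin, Cout, kernel = k, n_blocks = 1L)
  store <- wf_store()
  got <- crb_forward(x, spec, store, init_seed = 3L)

  conv_loop <- function(inp, W, b) {
    # W rows are laid out offset-major: k blocks of C_in channels
    Lh <- nrow(inp); C <- ncol(inp); h <- (k - 1) / 2
    out <- matrix(0, Lh, ncol(W))
    for (t in seq_len(Lh)) {
      acc <- as.numeric(b)
      for (o in -h:h) {
        src <- t + o
        if (src >= 1 && src <= Lh) {
          block <- ((o + h) * C + 1):((o + h + 1) * C)
          acc <- acc + as.numeric(inp[src, ] %*% W[block, , drop = FALSE])
        }
      }
      out[t, ] <- acc
    }
    out
  }
  y <- conv_loop(x, store[["crb.b1.conv1.W"]], store[["crb.b1.conv1.b"]])
  y <- ref_layernorm(y) * rep(as.numeric(store[["crb.b1.ln.gamma"]]), each = L) +
    rep(as.numeric(store[["crb.b1.ln.beta"]]), each = L)
  y <- ref_gelu(y)
  y <- conv_loop(y, store[["crb.b1.conv2.W"]], store[["crb.b1.conv2.b"]])
  expect_equal(got, y + x, tolerance = 1e-10)
})

test_that("extract_all aligns the three sources on d_model", {
  ds <- tiny_dataset(seed = 16L)
  sp <- split_dataset(ds, seed = 1L)
  model <- wf_model(tiny_model_config(), ds, sp, seed = 4L)
  embs <- extract_all(ds$records[[1]], model)
  expect_named(embs, c("rs", "cl", "so"))
  widths <- vapply(embs, ncol, 0L)
  expect_true(all(widths == model$config$d_model))
  expect_identical(nrow(embs$rs), 7L) # 9 months, window 3, stride 1
  expect_identical(nrow(embs$so), 8L) # dynamic tokens + 1 static token
  # static-only degenerate soil still yields a defined embedding
  r0 <- ds$records[[1]]
  r0$soil_dyn[] <- 0
  embs0 <- extract_all(r0, model)
  expect_gte(nrow(embs0$so), 1L)
  expect_true(all(is.finite(embs0$so)))
})

test_that("gradients flow to every extraction parameter", {
  ds <- tiny_dataset(seed = 17L)
  sp <- split_dataset(ds, seed = 1L)
  model <- wf_model(tiny_model_config(), ds, sp, seed = 5L)
  batch <- wf$make_batch(model, ds$records[sp$train[1:3]])
  head_of <- function() {
    ctx <- wf$nn_ctx(model$store, training = FALSE, init = FALSE)
    embs <- wf$.extract_all(ctx, batch, model$config)
    tot <- Reduce(wf$ag_add, lapply(embs, function(e)
      wf$ag_mean_all(wf$ag_square(e$node))))
    list(ctx = ctx, out = tot)
  }
  res <- head_of()
  grads <- wf$ag_backward(res$out)
  extraction_params <- grep("^(tfe_|crb_sos|lift_|stats_)",
                            ls(model$store), value = TRUE)
  for (nm in extraction_params) {
    expect_false(is.null(grads[[nm]]), info = nm)
  }
  # central-difference oracle on a sample of parameters, tol 1e-4
  set.seed(35)
  for (nm in sample(extraction_params, 6L)) {
    P <- model$store[[nm]]
    j <- sample(length(P), 1L)
    h <- 1e-5
    model$store[[nm]][j] <- P[j] + h
    up <- wf$ag_val(head_of()$out)[1]
    model$store[[nm]][j] <- P[j] - h
    dn <- wf$ag_val(head_of()$out)[1]
    model$store[[nm]][j] <- P[j]
    expect_equal(grads[[nm]][j], (up - dn) / (2 * h), tolerance = 1e-4,
                 info = nm)
  }
})
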
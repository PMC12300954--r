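# Yield prediction head: covariate assembly, positional encoding, graph
# attention oracle, encoder traces, FAN layer properties, and end-to-end
# prediction contracts.

test_that("positional encoding follows the sinusoidal closed form", {
  pe <- positional_encoding(5L, 8L)
  expect_equal(pe[1, 1], sin(0)) # position 0, even channel
  expect_equal(pe[1, 2], cos(0))
  expect_equal(pe[3, 1], sin(2)) # position index 2
  expect_equal(pe[2, 3], sin(1 * 10000^(-2 / 8))) # 0-based channel 2: sin
  expect_equal(pe[2, 4], cos(1 * 10000^(-2 / 8)))
  expect_true(all(abs(pe) <= 1))
})

test_that("assemble_input prepends exactly three covariate tokens", {
  ds <- tiny_dataset(seed = 19L)
  sp <- split_dataset(ds, seed = 1L)
  model <- wf_model(tiny_model_config(), ds, sp, seed = 7L)
  fused <- matrix(stats::rnorm(8 * 8), 8)
  asm <- assemble_input(fused, ds$records[[1]], model)
  expect_identical(dim(asm), c(11L, model$config$d_model))
  # with zero covariate projections the first three tokens reduce to the
  # positional encoding alone
  set_params(model$store, "^cov\\.")
  asm0 <- assemble_input(fused, ds$records[[1]], model)
  pe <- positional_encoding(11L, model$config$d_model)
  expect_equal(asm0[1:3, ], pe[1:3, ], tolerance = 1e-12)
})

test_that("token adjacency rules are symmetric with self-loops", {
  a <- token_adjacency(6L, "window_k", radius = 2L)
  expect_true(all(diag(a) == 1))
  expect_identical(a, t(a))
  expect_equal(a[1, 4], 0)
  expect_equal(a[1, 3], 1)
  expect_true(all(token_adjacency(4L, "full") == 1))
})

test_that("graph attention: singleton softmax, uniform case, loop oracle", {
  set.seed(51)
  d <- 4L
  x <- matrix(stats::rnorm(4 * d), 4)
  store <- wf_store()
  # self-loops only: every node attends to itself alone
  eye <- diag(4)
  out_self <- graph_attention(x, eye, store, init_seed = 1L)
  H <- x %*% store[["gat.v.W"]] + rep(as.numeric(store[["gat.v.b"]]), each = 4)
  expect_equal(out_self, H, tolerance = 1e-10)
  # all-equal scores on the full graph: uniform 1/n aggregation
  set_params(store, "^gat\\.a[12]\\.W$")
  out_unif <- graph_attention(x, matrix(1, 4, 4), store)
  expect_equal(out_unif, matrix(colMeans(H), 4, d, byrow = TRUE),
               tolerance = 1e-10)
  # chain adjacency (radius 1) against a per-node masked-softmax loop
  store2 <- wf_store()
  adj <- token_adjacency(4L, "window_k", radius = 1L)
  got <- graph_attention(x, adj, store2, init_seed = 2L)
  H2 <- x %*% store2[["gat.v.W"]] + rep(as.numeric(store2[["gat.v.b"]]), each = 4)
  s1 <- as.numeric(H2 %*% store2[["gat.a1.W"]])
  s2 <- as.numeric(H2 %*% store2[["gat.a2.W"]])
  lrelu <- function(v) ifelse(v > 0, v, 0.2 * v)
  want <- matrix(0, 4, d)
  for (i in 1:4) {
    nb <- which(adj[i, ] > 0)
    e <- lrelu(s1[i] + s2[nb])
    al <- ref_softmax(e)
    want[i, ] <- colSums(H2[nb, , drop = FALSE] * al)
  }
  expect_equal(got, want, tolerance = 1e-8)
  expect_error(graph_attention(x, diag(c(0, 1, 1, 1))), "self-loops")
  expect_error(graph_attention(x, upper.tri(diag(4)) * 1), "symmetric")
})

test_that("encoder with zero weights is layer normalization of the input", {
  set.seed(52)
  cfg <- tiny_model_config()
  x <- matrix(stats::rnorm(6 * cfg$d_model), 6)
  store <- wf_store()
  encoder_forward(x, cfg, store, init_seed = 3L)
  set_params(store, "^enc\\..*\\.(W|b)$")       # attention + FFN weights
  set_params(store, "^enc\\..*ln.\\.beta$")
  set_params(store, "^enc\\..*ln.\\.gamma$", 1)
  out <- encoder_forward(x, cfg, store)
  # residuals carry LN(x) through both layers; LN is idempotent on
  # already-normalized rows up to the epsilon correction
  expect_equal(out, ref_layernorm(ref_layernorm(x)), tolerance = 1e-6)
})

test_that("shape preservation for token counts 1..16 and exactly 2 layers", {
  cfg <- tiny_model_config()
  store <- wf_store()
  for (Tn in c(1L, 2L, 5L, 16L)) {
    out <- encoder_forward(matrix(0.1, Tn, cfg$d_model), cfg, wf_store(),
                           init_seed = Tn)
    expect_identical(dim(out), c(Tn, cfg$d_model))
  }
  encoder_forward(matrix(0.1, 4, cfg$d_model), cfg, store, init_seed = 1L)
  layers <- unique(sub("^enc\\.(l[0-9]+)\\..*$", "\\1",
                       grep("^enc\\.", ls(store), value = TRUE)))
  expect_setequal(layers, c("l1", "l2"))
  expect_error(model_config(d_model = 8L, n_heads = 3L), "divide")
})

test_that("disabling the graph branch reproduces a vanilla Transformer path", {
  set.seed(53)
  cfg_gat <- tiny_model_config(use_gat = TRUE)
  cfg_van <- tiny_model_config(use_gat = FALSE)
  x <- matrix(stats::rnorm(5 * cfg_gat$d_model), 5)
  store <- wf_store()
  out_gat <- encoder_forward(x, cfg_gat, store, init_seed = 4L)
  # zero the graph branch's value projection: its contribution vanishes
  set_params(store, "^enc\\.l[12]\\.gat\\.v\\.(W|b)$")
  out_zeroed <- encoder_forward(x, cfg_gat, store)
  out_vanilla <- encoder_forward(x, cfg_van, store)
  expect_identical(out_zeroed, out_vanilla)
  expect_false(identical(out_gat, out_vanilla))
})

test_that("FAN layer: cos/sin blocks, output width, periodicity", {
  set.seed(54)
  x <- matrix(stats::rnorm(6), 2, 3)
  store <- wf_store()
  out <- fan_forward(x, d_p = 2L, d_pbar = 3L, store = store, init_seed = 5L)
  expect_identical(ncol(out), 7L) # 2 * d_p + d_pbar
  expect_true(all(out[, 1:4] >= -1 & out[, 1:4] <= 1))
  # zero periodic projection: cos block all ones, sin block all zeros
  set_params(store, "^fan\\.p\\.W$")
  out0 <- fan_forward(x, 2L, 3L, store)
  expect_true(all(out0[, 1:2] == 1))
  expect_true(all(out0[, 3:4] == 0))
  # periodicity: shifting x so that Wp x moves by 2*pi leaves the
  # periodic blocks unchanged
  store2 <- wf_store()
  fan_forward(x, 3L, 2L, store2, init_seed = 6L)
  store2[["fan.p.W"]] <- diag(3)
  a <- fan_forward(x, 3L, 2L, store2)
  b <- fan_forward(x + matrix(c(2 * pi, 0, 0), 2, 3, byrow = TRUE),
                   3L, 2L, store2)
  expect_equal(a[, 1:6], b[, 1:6], tolerance = 1e-9)
})

test_that("predict is deterministic, respects the bias-only head trace", {
  ds <- tiny_dataset(seed = 20L)
  sp <- split_dataset(ds, seed = 1L)
  model <- wf_model(tiny_model_config(), ds, sp, seed = 8L)
  p1 <- predict(model, ds$records[sp$test[1:4]])
  p2 <- predict(model, ds$records[sp$test[1:4]])
  expect_identical(p1, p2)
  # zero final head: normalized prediction 0, de-normalized to train mean
  set_params(model$store, "^head\\.(W|b)$")
  p0 <- predict(model, ds$records[sp$test[1:3]])
  train_mean <- mean(vapply(ds$records[sp$train], `[[`, 0, "yield"))
  expect_equal(p0, rep(train_mean, 3L), tolerance = 1e-9)
})

test_that("prediction gradient w.r.t. an NDVI cell matches finite differences", {
  ds <- tiny_dataset(seed = 22L)
  sp <- split_dataset(ds, seed = 1L)
  model <- wf_model(tiny_model_config(), ds, sp, seed = 9L)
  batch <- wf$make_batch(model, ds$records[1:2])
  fwd <- function(b, want_grads = FALSE) {
    ctx <- wf$nn_ctx(model$store, training = FALSE, init = FALSE)
    ctx$want_input_grads <- want_grads
    out <- wf$ag_mean_all(wf$.forward(ctx, b, model$config))
    list(val = wf$ag_val(out)[1], out = out)
  }
  res <- fwd(batch, want_grads = TRUE)
  grads <- wf$ag_backward(res$out)
  cell <- c(3L, 1L) # march NDVI of the first record (normalized scale)
  h <- 1e-4
  up <- batch; up$rs[cell[1], cell[2]] <- up$rs[cell[1], cell[2]] + h
  dn <- batch; dn$rs[cell[1], cell[2]] <- dn$rs[cell[1], cell[2]] - h
  fd <- (fwd(up)$val - fwd(dn)$val) / (2 * h)
  expect_equal(grads[["input.rs"]][cell[1], cell[2]], fd,
               tolerance = 1e-3)
  expect_gt(abs(fd), 0)
})
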
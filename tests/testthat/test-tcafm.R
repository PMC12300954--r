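# Triple cross-attention fusion: Q/K projections, efficient additive
# attention against a loop oracle, structural contracts of the fused
# feature, the sigmoid/layer-norm gate trace, and relabeling equivariance.

test_that("the ordered pair set is exactly the 6 directed pairs", {
  p <- cross_pairs()
  expect_equal(nrow(p), 6L)
  expect_true(all(p$query != p$key))
  expect_equal(nrow(unique(p)), 6L)
  expect_setequal(paste(p$query, p$key),
                  c("rs cl", "rs so", "cl rs", "cl so", "so rs", "so cl"))
})

test_that("project_qk matches an explicit matrix-product oracle", {
  set.seed(41)
  emb <- matrix(stats::rnorm(12), 3, 4)
  store <- wf_store()
  qk <- project_qk(emb, d_attn = 4L, store = store, init_seed = 1L)
  expect_equal(qk$Q, emb %*% store[["pair.q.W"]] +
                 rep(as.numeric(store[["pair.q.b"]]), each = 3))
  expect_equal(qk$K, emb %*% store[["pair.k.W"]] +
                 rep(as.numeric(store[["pair.k.b"]]), each = 3))
  # zero weights: Q and K collapse to the bias broadcast
  set_params(store, "^pair\\..\\.W$")
  qk0 <- project_qk(emb, 4L, store)
  expect_equal(qk0$Q, matrix(store[["pair.q.b"]], 3, 4, byrow = TRUE))
  # identity weights, zero bias: Q equals the input
  store[["pair.q.W"]] <- diag(4)
  set_params(store, "^pair\\.q\\.b$")
  expect_equal(project_qk(emb, 4L, store)$Q, emb)
})

test_that("efficient additive attention follows the reference form", {
  set.seed(42)
  # single token: softmax of a singleton is exactly 1
  Q1 <- matrix(stats::rnorm(4), 1)
  out1 <- efficient_additive_attention(Q1, matrix(stats::rnorm(4), 1),
                                       init_seed = 2L)
  expect_equal(attr(out1, "alpha"), 1)
  # equal rows: uniform softmax 1/n
  Qe <- matrix(rep(stats::rnorm(3), each = 4), 4)
  oute <- efficient_additive_attention(Qe, matrix(stats::rnorm(12), 4),
                                       init_seed = 3L)
  expect_equal(attr(oute, "alpha"), rep(0.25, 4), tolerance = 1e-12)
  # softmax weights always sum to 1
  for (k in 1:5) {
    Q <- matrix(stats::rnorm(10), 5)
    out <- efficient_additive_attention(Q, matrix(stats::rnorm(10), 5),
                                        init_seed = k)
    expect_equal(sum(attr(out, "alpha")), 1, tolerance = 1e-6)
  }
})

test_that("attention output matches a brute-force loop oracle", {
  set.seed(43)
  Tn <- 3L; d <- 2L
  Q <- matrix(stats::rnorm(Tn * d, sd = 0.5), Tn)
  K <- matrix(stats::rnorm(Tn * d, sd = 0.5), Tn)
  store <- wf_store()
  got <- efficient_additive_attention(Q, K, store, init_seed = 4L)
  w <- store[["eaa.w"]]
  W_o <- store[["eaa.out.W"]]; b_o <- as.numeric(store[["eaa.out.b"]])
  # loop oracle: softmax, weighted sum, elementwise product, per token
  a <- numeric(Tn)
  for (i in seq_len(Tn)) a[i] <- sum(Q[i, ] * w) / sqrt(d)
  alpha <- ref_softmax(a)
  g <- numeric(d)
  for (i in seq_len(Tn)) g <- g + alpha[i] * Q[i, ]
  want <- matrix(0, Tn, d)
  for (i in seq_len(Tn)) {
    lin <- as.numeric((g * K[i, ]) %*% W_o) + b_o
    v <- Q[i, ] + lin
    want[i, ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  expect_equal(unclass(got), want, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(got, "alpha"), alpha, tolerance = 1e-10)
})

test_that("fusion concatenates 6 x d_attn channels and is deterministic", {
  set.seed(44)
  cfg <- tiny_model_config()
  rs <- matrix(stats::rnorm(7 * 8), 7)
  cl <- matrix(stats::rnorm(7 * 8), 7)
  so <- matrix(stats::rnorm(8 * 8), 8)
  store <- wf_store()
  out <- tcafm_fuse(rs, cl, so, cfg, store, init_seed = 5L)
  # token count aligns to the largest source
  expect_identical(dim(out), c(8L, cfg$d_model))
  # the CRB ingests 6 * d_attn channels (kernel x channels rows)
  expect_identical(nrow(store[["tcafm.crb.b1.conv1.W"]]),
                   cfg$crb_kernel * 6L * cfg$d_attn)
  # eval-mode dropout: repeated calls identical
  expect_identical(tcafm_fuse(rs, cl, so, cfg, store), out)
  expect_error(tcafm_fuse(rs, cl, so[, 1:4], cfg), "d_model")
})

test_that("gate trace: zero gate weights silence the fused feature", {
  # linear(0) = 0 -> relu -> linear(0) = 0 -> sigmoid = 1/2 everywhere;
  # layer norm of a constant vector is 0 (with epsilon), so the gate and
  # hence x_end vanish identically
  set.seed(45)
  cfg <- tiny_model_config()
  rs <- matrix(stats::rnorm(56), 7); cl <- matrix(stats::rnorm(56), 7)
  so <- matrix(stats::rnorm(64), 8)
  store <- wf_store()
  tcafm_fuse(rs, cl, so, cfg, store, init_seed = 6L)
  set_params(store, "^tcafm\\.gate\\.")
  out <- tcafm_fuse(rs, cl, so, cfg, store)
  expect_equal(max(abs(out)), 0)
})

test_that("swapping rs and cl with swapped parameters relabels the output", {
  set.seed(46)
  cfg <- tiny_model_config()
  d <- cfg$d_attn
  rs <- matrix(stats::rnorm(7 * 8), 7); cl <- matrix(stats::rnorm(7 * 8), 7)
  so <- matrix(stats::rnorm(8 * 8), 8)
  store <- wf_store()
  out <- tcafm_fuse(rs, cl, so, cfg, store, init_seed = 7L)
  # relabel rs <-> cl in every pair parameter name
  swap_src <- c(rs = "cl", cl = "rs", so = "so")
  swap_pair <- function(p) {
    q <- sub("_.*", "", p); k <- sub(".*_", "", p)
    paste0(swap_src[[q]], "_", swap_src[[k]])
  }
  swap_name <- function(nm) {
    m <- regmatches(nm, regexec("^tcafm\\.([a-z]+_[a-z]+)\\.", nm))[[1]]
    if (length(m) < 2) return(nm)
    sub(m[2], swap_pair(m[2]), nm, fixed = TRUE)
  }
  store2 <- wf_store()
  for (nm in ls(store)) store2[[swap_name(nm)]] <- store[[nm]]
  # the six attention outputs permute with the relabeling; realign the
  # channel blocks consumed by the first CRB conv (and its skip
  # projection) so the fused result is identical
  pairs <- paste0(cross_pairs()$query, "_", cross_pairs()$key)
  perm_blocks <- match(vapply(pairs, swap_pair, ""), pairs)
  chan_perm <- as.vector(vapply(perm_blocks, function(b)
    (b - 1L) * d + seq_len(d), integer(d)))
  k <- cfg$crb_kernel
  W <- store[["tcafm.crb.b1.conv1.W"]]
  rows <- as.vector(vapply(seq_len(k) - 1L, function(o)
    o * 6L * d + chan_perm, integer(6L * d)))
  store2[["tcafm.crb.b1.conv1.W"]] <- W[rows, , drop = FALSE]
  store2[["tcafm.crb.b1.proj.W"]] <-
    store[["tcafm.crb.b1.proj.W"]][chan_perm, , drop = FALSE]
  out2 <- tcafm_fuse(cl, rs, so, cfg, store2)
  expect_equal(out2, out, tolerance = 1e-10)
})

test_that("baseline fusion methods are drop-in alternatives", {
  ds <- tiny_dataset(seed = 18L)
  sp <- split_dataset(ds, seed = 1L)
  for (fusion in c("concat", "add", "avg", "max")) {
    cfg <- tiny_model_config(fusion = fusion)
    model <- wf_model(cfg, ds, sp, seed = 6L)
    p <- predict(model, ds$records[1:2])
    expect_length(p, 2L)
    expect_true(all(is.finite(p)))
  }
})
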
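# Reverse-mode automatic differentiation on dense numeric matrices.
#
# A tape records every primitive operation; ag_backward() replays it in
# reverse, accumulating gradients. Values are plain base-R matrices, so the
# whole engine rides on BLAS. Batches of samples that share a token count T
# are stacked sample-major into a (B*T) x D matrix; "group" ops (softmax,
# pooling, broadcast) interpret the row blocks.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- list()
  tp$parents <- list()
  tp$bws <- list()
  tp$leaf_name <- character(0) # names are node ids (as character)
  tp
}

ag_node <- function(tape, value, parents = integer(0), bw = NULL) {
  # Force arguments before allocating an id: R's lazy evaluation would
  # otherwise let nested calls create child nodes after this one, breaking
  # the tape's topological order.
  force(parents)
  force(value)
  i <- tape$n + 1L
  tape$n <- i
  tape$vals[[i]] <- value
  tape$parents[[i]] <- parents
  tape$bws[i] <- list(bw)
  list(tape = tape, id = i, value = value)
}

ag_val <- function(x) x$value

#' @noRd
ag_const <- function(tape, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ag_node(tape, x)
}

# Leaf holding a learnable parameter; gradients are collected under `name`.
ag_param <- function(tape, x, name) {
  nd <- ag_node(tape, x)
  tape$leaf_name[[as.character(nd$id)]] <- name
  nd
}

# Run the tape backwards from a scalar node; returns named list of gradients
# for every ag_param leaf (zero matrices for unused parameters are omitted).
ag_backward <- function(node) {
  tape <- node$tape
  stopifnot(length(ag_val(node)) == 1L)
  grads <- vector("list", tape$n)
  grads[[node$id]] <- matrix(1, 1, 1)
  for (i in seq.int(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bw <- tape$bws[[i]]
    if (is.null(bw)) next
    pg <- bw(g)
    ps <- tape$parents[[i]]
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      gk <- pg[[k]]
      if (is.null(gk)) next
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  out <- list()
  for (id_chr in names(tape$leaf_name)) {
    id <- as.integer(id_chr)
    nm <- tape$leaf_name[[id_chr]]
    g <- grads[[id]]
    if (is.null(g)) g <- matrix(0, nrow(tape$vals[[id]]), ncol(tape$vals[[id]]))
    out[[nm]] <- if (is.null(out[[nm]])) g else out[[nm]] + g
  }
  out
}

## ---- elementwise / linear primitives ----------------------------------

ag_matmul <- function(a, b) {
  A <- ag_val(a); B <- ag_val(b)
  ag_node(a$tape, A %*% B, c(a$id, b$id),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

ag_add <- function(a, b) {
  ag_node(a$tape, ag_val(a) + ag_val(b), c(a$id, b$id),
          function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$tape, ag_val(a) - ag_val(b), c(a$id, b$id),
          function(g) list(g, -g))
}

# a: n x d, bias: 1 x d broadcast over rows.
# rep(v, each = nrow) matches column-major layout, avoiding sweep().
ag_add_bias <- function(a, bias) {
  A <- ag_val(a); bv <- as.numeric(ag_val(bias))
  ag_node(a$tape, A + rep(bv, each = nrow(A)), c(a$id, bias$id),
          function(g) list(g, matrix(colSums(g), 1L)))
}

# a: n x d, gamma: 1 x d broadcast multiplicative
ag_mul_bias <- function(a, gamma) {
  A <- ag_val(a); gv <- as.numeric(ag_val(gamma))
  ag_node(a$tape, A * rep(gv, each = nrow(A)), c(a$id, gamma$id),
          function(g) list(g * rep(gv, each = nrow(g)),
                           matrix(colSums(g * A), 1L)))
}

ag_mul <- function(a, b) {
  A <- ag_val(a); B <- ag_val(b)
  ag_node(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

ag_scale <- function(a, s) {
  ag_node(a$tape, ag_val(a) * s, a$id, function(g) list(g * s))
}

ag_addc <- function(a, cmat) {
  ag_node(a$tape, ag_val(a) + cmat, a$id, function(g) list(g))
}

ag_mulc <- function(a, cmat) {
  ag_node(a$tape, ag_val(a) * cmat, a$id, function(g) list(g * cmat))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ag_val(a)))
  ag_node(a$tape, s, a$id, function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  t_ <- tanh(ag_val(a))
  ag_node(a$tape, t_, a$id, function(g) list(g * (1 - t_^2)))
}

ag_relu <- function(a) {
  A <- ag_val(a)
  ag_node(a$tape, pmax(A, 0), a$id, function(g) list(g * (A > 0)))
}

ag_leaky_relu <- function(a, alpha = 0.2) {
  A <- ag_val(a)
  ag_node(a$tape, ifelse(A > 0, A, alpha * A), a$id,
          function(g) list(g * ifelse(A > 0, 1, alpha)))
}

# Exact GELU: x * Phi(x); d/dx = Phi(x) + x * phi(x)
ag_gelu <- function(a) {
  A <- ag_val(a)
  P <- stats::pnorm(A)
  ag_node(a$tape, A * P, a$id,
          function(g) list(g * (P + A * stats::dnorm(A))))
}

ag_cos <- function(a) {
  A <- ag_val(a)
  ag_node(a$tape, cos(A), a$id, function(g) list(-g * sin(A)))
}

ag_sin <- function(a) {
  A <- ag_val(a)
  ag_node(a$tape, sin(A), a$id, function(g) list(g * cos(A)))
}

ag_square <- function(a) {
  A <- ag_val(a)
  ag_node(a$tape, A^2, a$id, function(g) list(2 * g * A))
}

# |x| with subgradient 0 at x = 0 (MAE loss)
ag_abs <- function(a) {
  A <- ag_val(a)
  ag_node(a$tape, abs(A), a$id, function(g) list(g * sign(A)))
}

ag_mean_all <- function(a) {
  A <- ag_val(a)
  n <- length(A)
  ag_node(a$tape, matrix(mean(A), 1, 1), a$id,
          function(g) list(matrix(g[1] / n, nrow(A), ncol(A))))
}

## ---- structural primitives --------------------------------------------

ag_cbind <- function(nodes) {
  tape <- nodes[[1]]$tape
  vals <- lapply(nodes, ag_val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(tape, do.call(cbind, vals), vapply(nodes, function(n) n$id, 1L),
          function(g) lapply(seq_along(widths),
                             function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

ag_cols <- function(a, idx) {
  A <- ag_val(a)
  ag_node(a$tape, A[, idx, drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, idx] <- g
    list(out)
  })
}

# Row gather; idx entries of 0 produce zero rows (used for zero padding).
ag_gather_rows <- function(a, idx) {
  A <- ag_val(a)
  sel <- idx > 0L
  V <- matrix(0, length(idx), ncol(A))
  V[sel, ] <- A[idx[sel], , drop = FALSE]
  ag_node(a$tape, V, a$id, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    if (any(sel)) {
      gs <- rowsum(g[sel, , drop = FALSE], group = idx[sel])
    rows <- as.integer(rownames(gs))
      out[rows, ] <- out[rows, ] + gs
    }
    list(out)
  })
}

# (B*T) x D -> B x D mean over each sample's T tokens
ag_group_mean_rows <- function(a, T_) {
  A <- ag_val(a)
  B <- nrow(A) / T_
  grp <- rep(seq_len(B), each = T_)
  ag_node(a$tape, rowsum(A, grp) / T_, a$id,
          function(g) list(g[grp, , drop = FALSE] / T_))
}

# B x D -> (B*T) x D, each sample row repeated T times
ag_repeat_rows <- function(a, T_) {
  A <- ag_val(a)
  idx <- rep(seq_len(nrow(A)), each = T_)
  ag_node(a$tape, A[idx, , drop = FALSE], a$id,
          function(g) list(rowsum(g, idx)))
}

# Softmax over each row (each row is one token's score vector)
ag_row_softmax <- function(a) {
  A <- ag_val(a)
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(A - m)
  S <- E / rowSums(E)
  ag_node(a$tape, S, a$id, function(g) {
    list((g - rowSums(g * S)) * S)
  })
}

# Softmax over each sample's block of T rows of a (B*T) x 1 score column.
ag_group_softmax <- function(a, T_) {
  A <- ag_val(a)
  stopifnot(ncol(A) == 1L)
  M <- matrix(A, nrow = T_) # T x B
  mx <- apply(M, 2L, max)
  E <- exp(sweep(M, 2L, mx))
  S <- sweep(E, 2L, colSums(E), "/")
  Sv <- matrix(as.numeric(S), ncol = 1L)
  ag_node(a$tape, Sv, a$id, function(g) {
    Gm <- matrix(g, nrow = T_)
    dot <- colSums(Gm * S)
    list(matrix((Gm - rep(dot, each = T_)) * S, ncol = 1L))
  })
}

# Per-sample weighted sum over tokens: alpha (B*T) x 1, x (B*T) x D -> B x D
ag_group_weighted_sum <- function(alpha, x, T_) {
  Av <- ag_val(alpha); X <- ag_val(x)
  B <- nrow(X) / T_
  grp <- rep(seq_len(B), each = T_)
  V <- rowsum(X * as.numeric(Av), grp)
  ag_node(alpha$tape, V, c(alpha$id, x$id), function(g) {
    Ge <- g[grp, , drop = FALSE]
    list(matrix(rowSums(Ge * X), ncol = 1L), Ge * as.numeric(Av))
  })
}

# Row-wise layer normalization, population variance, no affine terms.
ag_layernorm <- function(a, eps = 1e-5) {
  A <- ag_val(a)
  D <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  sg <- sqrt(rowMeans(xc^2) + eps)
  Y <- xc / sg
  ag_node(a$tape, Y, a$id, function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * Y)
    list((g - gm - Y * gy) / sg)
  })
}

# Batched matrix multiply over B sample blocks of T rows.
# x: (B*T) x D. If transpose_y: y (B*T) x D -> result (B*T) x T (scores);
# else y is (B*T_y) x D with ncol(x) == T_y (attention application).
ag_bmm <- function(x, y, T_, transpose_y = FALSE) {
  X <- ag_val(x); Y <- ag_val(y)
  if (transpose_y) {
    B <- nrow(X) / T_
    V <- matrix(0, nrow(X), T_)
    for (b in seq_len(B)) {
      r <- ((b - 1L) * T_ + 1L):(b * T_)
      V[r, ] <- tcrossprod(X[r, , drop = FALSE], Y[r, , drop = FALSE])
    }
    ag_node(x$tape, V, c(x$id, y$id), function(g) {
      gx <- matrix(0, nrow(X), ncol(X)); gy <- matrix(0, nrow(Y), ncol(Y))
      for (b in seq_len(B)) {
        r <- ((b - 1L) * T_ + 1L):(b * T_)
        gx[r, ] <- g[r, , drop = FALSE] %*% Y[r, , drop = FALSE]
        gy[r, ] <- crossprod(g[r, , drop = FALSE], X[r, , drop = FALSE])
      }
      list(gx, gy)
    })
  } else {
    T_y <- ncol(X)
    B <- nrow(X) / T_
    stopifnot(nrow(Y) == B * T_y)
    V <- matrix(0, nrow(X), ncol(Y))
    for (b in seq_len(B)) {
      rx <- ((b - 1L) * T_ + 1L):(b * T_)
      ry <- ((b - 1L) * T_y + 1L):(b * T_y)
      V[rx, ] <- X[rx, , drop = FALSE] %*% Y[ry, , drop = FALSE]
    }
    ag_node(x$tape, V, c(x$id, y$id), function(g) {
      gx <- matrix(0, nrow(X), ncol(X)); gy <- matrix(0, nrow(Y), ncol(Y))
      for (b in seq_len(B)) {
        rx <- ((b - 1L) * T_ + 1L):(b * T_)
        ry <- ((b - 1L) * T_y + 1L):(b * T_y)
        gx[rx, ] <- tcrossprod(g[rx, , drop = FALSE], Y[ry, , drop = FALSE])
        gy[ry, ] <- crossprod(X[rx, , drop = FALSE], g[rx, , drop = FALSE])
      }
      list(gx, gy)
    })
  }
}

# Inverted dropout; `mask` supplied by caller so randomness stays seeded.
ag_dropout <- function(a, p, training, mask = NULL) {
  if (!training || p <= 0) return(a)
  A <- ag_val(a)
  if (is.null(mask)) {
    mask <- matrix(stats::rbinom(length(A), 1L, 1 - p), nrow(A)) / (1 - p)
  }
  ag_mulc(a, mask)
}

ag_rbind <- function(nodes) {
  tape <- nodes[[1]]$tape
  vals <- lapply(nodes, ag_val)
  heights <- vapply(vals, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_node(tape, do.call(rbind, vals), vapply(nodes, function(n) n$id, 1L),
          function(g) lapply(seq_along(heights),
                             function(k) g[starts[k]:ends[k], , drop = FALSE]))
}

# Elementwise maximum; ties route the gradient to the first argument.
ag_max2 <- function(a, b) {
  A <- ag_val(a); B <- ag_val(b)
  take_a <- A >= B
  ag_node(a$tape, pmax(A, B), c(a$id, b$id),
          function(g) list(g * take_a, g * !take_a))
}

## ---- fused compound nodes ---------------------------------------------
# Single-node versions of hot compound ops. Functionally identical to the
# primitive compositions; fused to cut tape length and allocations.

# x %*% W + b in one node (b optional)
ag_linear <- function(x, W, b = NULL) {
  X <- ag_val(x); Wv <- ag_val(W)
  V <- X %*% Wv
  if (is.null(b)) {
    ag_node(x$tape, V, c(x$id, W$id),
            function(g) list(g %*% t(Wv), crossprod(X, g)))
  } else {
    V <- V + rep(as.numeric(ag_val(b)), each = nrow(V))
    ag_node(x$tape, V, c(x$id, W$id, b$id),
            function(g) list(g %*% t(Wv), crossprod(X, g),
                             matrix(colSums(g), 1L)))
  }
}

# gamma * (x - mean) / sqrt(var + eps) + beta, row-wise, one node
ag_layernorm_affine <- function(x, gamma, beta, eps = 1e-5) {
  X <- ag_val(x)
  gv <- as.numeric(ag_val(gamma)); bv <- as.numeric(ag_val(beta))
  mu <- rowMeans(X)
  xc <- X - mu
  sg <- sqrt(rowMeans(xc^2) + eps)
  Y0 <- xc / sg
  n <- nrow(X)
  V <- Y0 * rep(gv, each = n) + rep(bv, each = n)
  ag_node(x$tape, V, c(x$id, gamma$id, beta$id), function(g) {
    gy <- g * rep(gv, each = n)
    list((gy - rowMeans(gy) - Y0 * rowMeans(gy * Y0)) / sg,
         matrix(colSums(g * Y0), 1L),
         matrix(colSums(g), 1L))
  })
}

# One fused GRU step. Parameters follow the standard gate layout with
# columns [r | z | n] in W_x (d_in x 3H), W_h (H x 3H), b_x, b_h (1 x 3H):
#   r = sigmoid(x Wx_r + bx_r + h Wh_r + bh_r)
#   z = sigmoid(x Wx_z + bx_z + h Wh_z + bh_z)
#   n = tanh(x Wx_n + bx_n + r * (h Wh_n + bh_n))
#   h' = (1 - z) * n + z * h
ag_gru_step <- function(x, h, W_x, W_h, b_x, b_h) {
  X <- ag_val(x); H <- ag_val(h)
  Wx <- ag_val(W_x); Wh <- ag_val(W_h)
  nH <- ncol(Wx) / 3L
  nr <- nrow(X)
  gx <- X %*% Wx + rep(as.numeric(ag_val(b_x)), each = nr)
  gh <- H %*% Wh + rep(as.numeric(ag_val(b_h)), each = nr)
  ir <- seq_len(nH); iz <- ir + nH; in_ <- iz + nH
  r <- 1 / (1 + exp(-(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])))
  z <- 1 / (1 + exp(-(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE])))
  u <- gh[, in_, drop = FALSE]
  n_ <- tanh(gx[, in_, drop = FALSE] + r * u)
  V <- (1 - z) * n_ + z * H
  ag_node(x$tape, V, c(x$id, h$id, W_x$id, W_h$id, b_x$id, b_h$id),
          function(g) {
    dz <- g * (H - n_)
    dan <- g * (1 - z) * (1 - n_^2)
    dr <- dan * u
    du <- dan * r
    daz <- dz * z * (1 - z)
    dar <- dr * r * (1 - r)
    dGx <- cbind(dar, daz, dan)      # grads wrt x-side pre-activations
    dGh <- cbind(dar, daz, du)       # grads wrt h-side pre-activations
    list(dGx %*% t(Wx),
         dGh %*% t(Wh) + g * z,
         crossprod(X, dGx),
         crossprod(H, dGh),
         matrix(colSums(dGx), 1L),
         matrix(colSums(dGh), 1L))
  })
}

# Unfold a (B*T) x C sample-major token matrix into the k shifted views
# used by a same-padded width-k convolution: one node, output
# (B*T) x (k*C), zero padding outside each sample block.
ag_unfold <- function(x, T_, k) {
  X <- ag_val(x)
  B <- nrow(X) / T_
  h <- (k - 1L) %/% 2L
  offs <- seq.int(-h, h)
  idxs <- lapply(offs, function(o) if (o == 0L) NULL else shift_idx(B, T_, o))
  C <- ncol(X)
  V <- matrix(0, nrow(X), k * C)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (is.null(idxs[[j]])) V[, cols] <- X
    else {
      sel <- idxs[[j]] > 0L
      V[sel, cols] <- X[idxs[[j]][sel], , drop = FALSE]
    }
  }
  ag_node(x$tape, V, x$id, function(g) {
    out <- matrix(0, nrow(X), C)
    for (j in seq_len(k)) {
      cols <- ((j - 1L) * C + 1L):(j * C)
      if (is.null(idxs[[j]])) out <- out + g[, cols, drop = FALSE]
      else {
        sel <- idxs[[j]] > 0L
        gs <- rowsum(g[sel, cols, drop = FALSE], group = idxs[[j]][sel])
        rows <- as.integer(rownames(gs))
        out[rows, ] <- out[rows, ] + gs
      }
    }
    list(out)
  })
}
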
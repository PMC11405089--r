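# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records operations in execution order (which is already a valid
# topological order), and ad_backward() walks it in reverse, accumulating
# gradients into node environments. All values are base-R numeric matrices;
# scalars are 1x1 matrices. The engine exists so the encoders, score networks
# and losses in this package are trainable without an external deep-learning
# runtime; it is deliberately small and single-threaded deterministic.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

is_ad <- function(x) is.environment(x) && isTRUE(x$.ad)

ad_val <- function(x) if (is_ad(x)) x$value else x

ad_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$.ad <- TRUE
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# Leaf with gradient tracking (parameters, or inputs differentiated w.r.t.).
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_acc <- function(nd, g) {
  if (!is_ad(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run reverse pass from a scalar node. Seeds with gradient 1.
ad_backward <- function(tape, loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

## ---- elementary operations -------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, av %*% bv)
  out$backfn <- function(g) {
    if (is_ad(a)) ad_acc(a, g %*% t(bv))
    if (is_ad(b)) ad_acc(b, crossprod(av, g))
  }
  out
}

ad_add <- function(tape, a, b) {
  out <- ad_node(tape, ad_val(a) + ad_val(b))
  out$backfn <- function(g) { ad_acc(a, g); ad_acc(b, g) }
  out
}

ad_sub <- function(tape, a, b) {
  out <- ad_node(tape, ad_val(a) - ad_val(b))
  out$backfn <- function(g) { ad_acc(a, g); ad_acc(b, -g) }
  out
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, av * bv)
  out$backfn <- function(g) {
    if (is_ad(a)) ad_acc(a, g * bv)
    if (is_ad(b)) ad_acc(b, g * av)
  }
  out
}

ad_div <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, av / bv)
  out$backfn <- function(g) {
    if (is_ad(a)) ad_acc(a, g / bv)
    if (is_ad(b)) ad_acc(b, -g * av / (bv * bv))
  }
  out
}

# Add a 1 x k row vector to every row of an n x k matrix (bias add).
ad_add_rowvec <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, sweep(av, 2L, as.numeric(bv), "+"))
  out$backfn <- function(g) {
    ad_acc(a, g)
    if (is_ad(b)) ad_acc(b, matrix(colSums(g), 1L))
  }
  out
}

# Multiply every row of an n x k matrix by a 1 x k row vector (scale).
ad_mul_rowvec <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, sweep(av, 2L, as.numeric(bv), "*"))
  out$backfn <- function(g) {
    if (is_ad(a)) ad_acc(a, sweep(g, 2L, as.numeric(bv), "*"))
    if (is_ad(b)) ad_acc(b, matrix(colSums(g * av), 1L))
  }
  out
}

# a * mult + shift with plain-numeric mult/shift (no gradient through them).
ad_affine <- function(tape, a, mult = 1, shift = 0) {
  out <- ad_node(tape, ad_val(a) * mult + shift)
  out$backfn <- function(g) ad_acc(a, g * mult)
  out
}

ad_unary <- function(tape, a, fwd, dfun) {
  av <- ad_val(a)
  ov <- fwd(av)
  out <- ad_node(tape, ov)
  out$backfn <- function(g) ad_acc(a, g * dfun(av, ov))
  out
}

ad_sigmoid <- function(tape, a) ad_unary(tape, a, function(x) 1 / (1 + exp(-x)),
                                         function(x, y) y * (1 - y))
ad_tanh    <- function(tape, a) ad_unary(tape, a, tanh, function(x, y) 1 - y * y)
ad_relu    <- function(tape, a) ad_unary(tape, a, function(x) pmax(x, 0),
                                         function(x, y) (x > 0) + 0)
ad_exp     <- function(tape, a) ad_unary(tape, a, exp, function(x, y) y)
ad_log     <- function(tape, a) ad_unary(tape, a, log, function(x, y) 1 / x)
ad_sqrt    <- function(tape, a) ad_unary(tape, a, sqrt, function(x, y) 0.5 / y)
ad_square  <- function(tape, a) ad_unary(tape, a, function(x) x * x, function(x, y) 2 * x)

# Numerically stable softplus log(1 + exp(x)); gradient is sigmoid(x).
ad_softplus <- function(tape, a) {
  ad_unary(tape, a, function(x) pmax(x, 0) + log1p(exp(-abs(x))),
           function(x, y) 1 / (1 + exp(-x)))
}

ad_transpose <- function(tape, a) {
  out <- ad_node(tape, t(ad_val(a)))
  out$backfn <- function(g) ad_acc(a, t(g))
  out
}

# a %*% t(b) without materializing a transposed node.
ad_matmul_t <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_node(tape, tcrossprod(av, bv))
  out$backfn <- function(g) {
    if (is_ad(a)) ad_acc(a, g %*% bv)
    if (is_ad(b)) ad_acc(b, crossprod(g, av))
  }
  out
}

ad_sum <- function(tape, a) {
  av <- ad_val(a)
  out <- ad_node(tape, matrix(sum(av), 1L, 1L))
  out$backfn <- function(g) ad_acc(a, matrix(as.numeric(g), nrow(av), ncol(av)))
  out
}

ad_mean <- function(tape, a) {
  av <- ad_val(a)
  n <- length(av)
  out <- ad_node(tape, matrix(sum(av) / n, 1L, 1L))
  out$backfn <- function(g) ad_acc(a, matrix(as.numeric(g) / n, nrow(av), ncol(av)))
  out
}

ad_rowsums <- function(tape, a) {
  av <- ad_val(a)
  out <- ad_node(tape, matrix(rowSums(av), ncol = 1L))
  out$backfn <- function(g) ad_acc(a, matrix(g, nrow(av), ncol(av)))
  out
}

ad_colmeans <- function(tape, a) {
  av <- ad_val(a)
  n <- nrow(av)
  out <- ad_node(tape, matrix(colMeans(av), 1L))
  out$backfn <- function(g) ad_acc(a, matrix(g, n, ncol(av), byrow = TRUE) / n)
  out
}

# Row gather: out[i, ] = a[idx[i], ].
ad_gather_rows <- function(tape, a, idx) {
  av <- ad_val(a)
  idx <- as.integer(idx)
  out <- ad_node(tape, av[idx, , drop = FALSE])
  out$backfn <- function(g) {
    if (!is_ad(a)) return(invisible(NULL))
    ad_acc(a, dense_rowsum(g, idx, nrow(av)))
  }
  out
}

# Scatter-sum rows into ngroups rows: out[g, ] = sum of rows with groups == g.
ad_scatter_sum <- function(tape, a, groups, ngroups) {
  av <- ad_val(a)
  groups <- as.integer(groups)
  out <- ad_node(tape, dense_rowsum(av, groups, ngroups))
  out$backfn <- function(g) ad_acc(a, g[groups, , drop = FALSE])
  out
}

# rowsum() with empty groups kept as zero rows, rows ordered 1..n.
dense_rowsum <- function(x, groups, n) {
  m <- matrix(0, n, ncol(x))
  r <- rowsum(x, groups)
  m[as.integer(rownames(r)), ] <- r
  m
}

# Sum columns within H contiguous equal-width blocks: n x (H*B) -> n x H.
ad_rowsum_blocks <- function(tape, a, H) {
  av <- ad_val(a)
  n <- nrow(av); B <- ncol(av) %/% H
  fwd <- function(x) {
    dim(x) <- c(n, B, H)  # columns are laid out block-major: block h spans (h-1)*B+1 .. h*B
    apply(x, c(1L, 3L), sum)
  }
  ov <- fwd(av)
  out <- ad_node(tape, ov)
  out$backfn <- function(g) ad_acc(a, g[, rep(seq_len(H), each = B), drop = FALSE])
  out
}

# Repeat each of the H columns B times: n x H -> n x (H*B). Inverse of above.
ad_expand_blocks <- function(tape, a, B) {
  av <- ad_val(a)
  H <- ncol(av)
  out <- ad_node(tape, av[, rep(seq_len(H), each = B), drop = FALSE])
  out$backfn <- function(g) {
    n <- nrow(g)
    dim(g) <- c(n, B, H)
    ad_acc(a, apply(g, c(1L, 3L), sum))
  }
  out
}

ad_concat_cols <- function(tape, parts) {
  vals <- lapply(parts, ad_val)
  out <- ad_node(tape, do.call(cbind, vals))
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out$backfn <- function(g) {
    for (i in seq_along(parts)) {
      if (is_ad(parts[[i]])) ad_acc(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  }
  out
}

ad_concat_rows <- function(tape, parts) {
  vals <- lapply(parts, ad_val)
  out <- ad_node(tape, do.call(rbind, vals))
  heights <- vapply(vals, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  out$backfn <- function(g) {
    for (i in seq_along(parts)) {
      if (is_ad(parts[[i]])) ad_acc(parts[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  }
  out
}

# Column gather (with repeats): out[, j] = a[, idx[j]].
ad_index_cols <- function(tape, a, idx) {
  av <- ad_val(a)
  idx <- as.integer(idx)
  out <- ad_node(tape, av[, idx, drop = FALSE])
  out$backfn <- function(g) {
    if (!is_ad(a)) return(invisible(NULL))
    acc <- t(dense_rowsum(t(g), idx, ncol(av)))
    ad_acc(a, acc)
  }
  out
}

ad_slice_cols <- function(tape, a, j) {
  av <- ad_val(a)
  out <- ad_node(tape, av[, j, drop = FALSE])
  out$backfn <- function(g) {
    if (!is_ad(a)) return(invisible(NULL))
    full <- matrix(0, nrow(av), ncol(av))
    full[, j] <- g
    ad_acc(a, full)
  }
  out
}

# Row-wise layer normalization with learned gain/shift (1 x k each).
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  av <- ad_val(a)
  k <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(ad_val(gamma)); bv <- as.numeric(ad_val(beta))
  out <- ad_node(tape, sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+"))
  out$backfn <- function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    if (is_ad(a)) {
      t1 <- rowMeans(dxhat)
      t2 <- rowMeans(dxhat * xhat)
      ad_acc(a, inv * (dxhat - t1 - xhat * t2))
    }
    if (is_ad(gamma)) ad_acc(gamma, matrix(colSums(g * xhat), 1L))
    if (is_ad(beta)) ad_acc(beta, matrix(colSums(g), 1L))
  }
  out
}

# Numerically stable row-wise log-softmax.
ad_logsoftmax_rows <- function(tape, a) {
  av <- ad_val(a)
  m <- apply(av, 1L, max)
  z <- av - m
  lse <- log(rowSums(exp(z)))
  ov <- z - lse
  out <- ad_node(tape, ov)
  out$backfn <- function(g) ad_acc(a, g - exp(ov) * rowSums(g))
  out
}

# Softmax over rows sharing a group id (grouped attention normalization).
# x is n x H (independent softmax per column within each group).
ad_group_softmax <- function(tape, x, groups, ngroups) {
  xv <- ad_val(x)
  groups <- as.integer(groups)
  # detached per-group max for stability (constant shift; exact gradient kept)
  mx <- apply(xv, 2L, function(col) {
    m <- tapply(col, groups, max)
    as.numeric(m[as.character(groups)])
  })
  if (is.null(dim(mx))) mx <- matrix(mx, nrow = nrow(xv))
  e <- ad_exp(tape, ad_affine(tape, x, 1, -mx))
  s <- ad_scatter_sum(tape, e, groups, ngroups)
  ad_div(tape, e, ad_gather_rows(tape, s, groups))
}

## ---- parameter store, layers, optimizer ------------------------------------

ps_new <- function() {
  ps <- new.env(parent = emptyenv())
  ps$val <- list()
  ps$adam_m <- list()
  ps$adam_v <- list()
  ps$adam_t <- 0L
  ps
}

ps_add <- function(ps, name, value) {
  ps$val[[name]] <- value
  invisible(ps)
}

# Glorot-uniform init for a d_in x d_out weight.
glorot <- function(d_in, d_out) {
  r <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out)
}

# Register a linear layer's parameters under <prefix>.W / <prefix>.b.
ps_add_linear <- function(ps, prefix, d_in, d_out, zero = FALSE) {
  ps_add(ps, paste0(prefix, ".W"), if (zero) matrix(0, d_in, d_out) else glorot(d_in, d_out))
  ps_add(ps, paste0(prefix, ".b"), matrix(0, 1L, d_out))
  invisible(ps)
}

ps_add_layernorm <- function(ps, prefix, k) {
  ps_add(ps, paste0(prefix, ".g"), matrix(1, 1L, k))
  ps_add(ps, paste0(prefix, ".s"), matrix(0, 1L, k))
  invisible(ps)
}

# An MLP with dims c(d_in, h1, ..., d_out); relu between layers.
ps_add_mlp <- function(ps, prefix, dims, zero_last = FALSE) {
  for (i in seq_len(length(dims) - 1L)) {
    ps_add_linear(ps, paste0(prefix, ".l", i), dims[i], dims[i + 1L],
                  zero = zero_last && i == length(dims) - 1L)
  }
  invisible(ps)
}

# Materialize tracked leaf nodes for every parameter on a tape.
ps_leaves <- function(tape, ps) {
  P <- new.env(parent = emptyenv())
  for (nm in names(ps$val)) assign(nm, ad_leaf(tape, ps$val[[nm]]), envir = P)
  P
}

pget <- function(P, name) {
  if (is.environment(P)) get(name, envir = P, inherits = FALSE) else P[[name]]
}

nn_linear <- function(tape, P, prefix, x) {
  ad_add_rowvec(tape, ad_matmul(tape, x, pget(P, paste0(prefix, ".W"))),
                pget(P, paste0(prefix, ".b")))
}

nn_layernorm <- function(tape, P, prefix, x) {
  ad_layernorm(tape, x, pget(P, paste0(prefix, ".g")), pget(P, paste0(prefix, ".s")))
}

nn_mlp <- function(tape, P, prefix, x, n_layers) {
  for (i in seq_len(n_layers)) {
    x <- nn_linear(tape, P, paste0(prefix, ".l", i), x)
    if (i < n_layers) x <- ad_relu(tape, x)
  }
  x
}

# Collect gradients from leaves back into a named list (zeros where untouched).
ps_grads <- function(ps, P) {
  out <- list()
  for (nm in names(ps$val)) {
    nd <- get(nm, envir = P, inherits = FALSE)
    out[[nm]] <- if (is.null(nd$grad)) ps$val[[nm]] * 0 else nd$grad
  }
  out
}

# One Adam update, with global gradient-norm clipping.
adam_step <- function(ps, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  ps$adam_t <- ps$adam_t + 1L
  t <- ps$adam_t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(ps$adam_m[[nm]])) {
      ps$adam_m[[nm]] <- g * 0
      ps$adam_v[[nm]] <- g * 0
    }
    ps$adam_m[[nm]] <- beta1 * ps$adam_m[[nm]] + (1 - beta1) * g
    ps$adam_v[[nm]] <- beta2 * ps$adam_v[[nm]] + (1 - beta2) * g * g
    mhat <- ps$adam_m[[nm]] / (1 - beta1^t)
    vhat <- ps$adam_v[[nm]] / (1 - beta2^t)
    ps$val[[nm]] <- ps$val[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(ps)
}

# Derive a child seed from a base seed and a stream label (stays under 2^31).
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x)
}
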
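# Geometric triangle-awareness encoders.
#
# Both encoders share a block of four updates: node-to-edge, a multiplicative
# triangle (edge-to-edge) update, an attention triangle update in which the
# third edge of each triangle enters the attention score as a bias, and an
# edge-to-node update aggregating separately along rows and columns of the
# pair array. The 2D encoder is initialized with two bond-aware GIN layers
# (two-hop topology); the 3D encoder with one continuous-filter convolution
# over radial-basis-expanded interatomic distances, so it sees coordinates
# only through the distance map and is rigid-motion invariant by construction.

#' Encoder configuration
#'
#' @param D_h node embedding width.
#' @param D_z pair (edge) embedding width; must be divisible by `n_heads`.
#' @param n_blocks number of triangle-awareness blocks.
#' @param n_heads attention heads in the triangle attention update. With 1
#'   head the update is exactly the single-head printed form.
#' @param mlp_hidden hidden width of the 3-layer edge-to-node MLPs.
#' @param pool_dim width of the pooled molecule-level embedding (256).
#' @param n_rbf,rbf_max radial basis size and range (Angstrom) for the 3D
#'   distance expansion.
#' @param w2d admissible third-vertex set for 2D triangles:
#'   `"intersection"` (both incident pair embeddings exist: N(u) & N(v)) or
#'   `"union"` (the literal N(u) | N(v), with missing 2D pair embeddings
#'   materialized as a learned null vector).
#' @param product how node features combine in the node-to-edge update:
#'   `"elementwise"` (commutative, default) or `"outer"` (flattened outer
#'   product).
#' @export
encoder_config <- function(D_h = 128L, D_z = 128L, n_blocks = 3L, n_heads = 4L,
                           mlp_hidden = 64L, pool_dim = 256L,
                           n_rbf = 16L, rbf_max = 5.0,
                           w2d = c("intersection", "union"),
                           product = c("elementwise", "outer")) {
  w2d <- match.arg(w2d)
  product <- match.arg(product)
  stopifnot(D_h >= 1L, D_z >= 1L, n_blocks >= 0L, n_heads >= 1L,
            D_z %% n_heads == 0L, mlp_hidden >= 1L, pool_dim >= 1L)
  structure(list(D_h = as.integer(D_h), D_z = as.integer(D_z),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 pool_dim = as.integer(pool_dim),
                 n_rbf = as.integer(n_rbf), rbf_max = rbf_max,
                 w2d = w2d, product = product),
            class = "encoder_config")
}

N_NODE_FEAT <- 13L  # element one-hot (11) + formal charge + aromatic flag
N_BOND_FEAT <- 4L

featurize_nodes_2d <- function(g2d) {
  idx <- match(g2d$elements, ELEMENT_VOCAB)
  if (anyNA(idx)) {
    warning("unknown element(s) ", paste(unique(g2d$elements[is.na(idx)]), collapse = ","),
            " mapped to 'other'", call. = FALSE)
    idx[is.na(idx)] <- length(ELEMENT_VOCAB)
  }
  m <- matrix(0, g2d$n, N_NODE_FEAT)
  m[cbind(seq_len(g2d$n), idx)] <- 1
  m[, 12L] <- g2d$charges
  m[, 13L] <- as.numeric(g2d$aromatic)
  m
}

featurize_bonds <- function(types) {
  m <- matrix(0, length(types), N_BOND_FEAT)
  if (length(types)) m[cbind(seq_along(types), types)] <- 1
  m
}

featurize_nodes_3d <- function(g3d) {
  el <- element_from_z(g3d$z)
  idx <- match(el, ELEMENT_VOCAB, nomatch = length(ELEMENT_VOCAB))
  m <- matrix(0, g3d$n, length(ELEMENT_VOCAB))
  m[cbind(seq_len(g3d$n), idx)] <- 1
  m
}

rbf_centers <- function(cfg) seq(0, cfg$rbf_max, length.out = cfg$n_rbf)
rbf_gamma <- function(cfg) {
  spacing <- cfg$rbf_max / (cfg$n_rbf - 1L)
  1 / (2 * spacing^2)
}

## ---- batched graph structures ----------------------------------------------

# Triples carry, per admissible (u,v,w), the pair ids needed by both triangle
# updates: uv (destination), uw, vw, and the attention's printed index pattern
# kw<-(w,v), b<-(w,u). Missing 2D pairs (union mode) point at the null slot
# npairs + 1.
build_triples <- function(pid, pairs_u, pairs_v, nbrs, mode, null_id) {
  g <- integer(0); uw <- integer(0); vw <- integer(0)
  wv <- integer(0); wu <- integer(0)
  for (p in seq_along(pairs_u)) {
    u <- pairs_u[p]; v <- pairs_v[p]
    W <- if (mode == "all") {
      setdiff(nbrs, c(u, v))  # nbrs is the molecule's node set here
    } else if (mode == "intersection") {
      intersect(nbrs[[u]], setdiff(nbrs[[v]], c(u, v)))
    } else {
      setdiff(union(nbrs[[u]], nbrs[[v]]), c(u, v))
    }
    if (length(W) == 0L) next
    lk <- function(a, b) {
      id <- pid[cbind(a, b)]
      id[id == 0L] <- null_id
      id
    }
    g <- c(g, rep.int(p, length(W)))
    uw <- c(uw, lk(rep.int(u, length(W)), W))
    vw <- c(vw, lk(rep.int(v, length(W)), W))
    wv <- c(wv, lk(W, rep.int(v, length(W))))
    wu <- c(wu, lk(W, rep.int(u, length(W))))
  }
  list(group = g, p_uw = uw, p_vw = vw, p_wv = wv, p_wu = wu)
}

# Assemble a block-diagonal batch over 2D graphs: bonded ordered pairs only.
build_batch2d <- function(g2ds, cfg) {
  ns <- vapply(g2ds, function(g) g$n, 1L)
  off <- cumsum(c(0L, utils::head(ns, -1L)))
  n_tot <- sum(ns)
  node_feat <- do.call(rbind, lapply(g2ds, featurize_nodes_2d))
  mol_id <- rep(seq_along(g2ds), ns)
  pu <- integer(0); pv <- integer(0); pt <- integer(0); pm <- integer(0)
  for (i in seq_along(g2ds)) {
    g <- g2ds[[i]]
    pu <- c(pu, g$bond_u + off[i]); pv <- c(pv, g$bond_v + off[i])
    pt <- c(pt, g$bond_type); pm <- c(pm, rep.int(i, length(g$bond_u)))
  }
  npairs <- length(pu)
  pid <- matrix(0L, n_tot, n_tot)
  if (npairs) pid[cbind(pu, pv)] <- seq_len(npairs)
  null_id <- npairs + 1L
  tg <- integer(0); tuw <- integer(0); tvw <- integer(0)
  twv <- integer(0); twu <- integer(0)
  nbrs <- vector("list", n_tot)
  for (i in seq_along(g2ds)) {
    nbrs[off[i] + seq_len(ns[i])] <-
      lapply(neighbor_map(g2ds[[i]]), function(x) x + off[i])
  }
  for (i in seq_along(g2ds)) {
    local_pairs <- which(pm == i)
    tr <- build_triples(pid, pu[local_pairs], pv[local_pairs], nbrs,
                        mode = cfg$w2d, null_id = null_id)
    tg <- c(tg, local_pairs[tr$group])
    tuw <- c(tuw, tr$p_uw); tvw <- c(tvw, tr$p_vw)
    twv <- c(twv, tr$p_wv); twu <- c(twu, tr$p_wu)
  }
  list(n = n_tot, mol_id = mol_id, n_mol = length(g2ds), mol_sizes = ns,
       node_feat = node_feat,
       pairs = list(u = pu, v = pv, type = pt, mol = pm, n = npairs),
       pid = pid,
       triples = list(group = tg, p_uw = tuw, p_vw = tvw, p_wv = twv, p_wu = twu),
       has_null = cfg$w2d == "union")
}

# Fully connected batch over 3D graphs: all ordered pairs within a molecule.
build_batch3d <- function(g3ds, cfg) {
  ns <- vapply(g3ds, function(g) g$n, 1L)
  off <- cumsum(c(0L, utils::head(ns, -1L)))
  n_tot <- sum(ns)
  node_feat <- do.call(rbind, lapply(g3ds, featurize_nodes_3d))
  mol_id <- rep(seq_along(g3ds), ns)
  coords <- do.call(rbind, lapply(g3ds, function(g) g$coords))
  pu <- integer(0); pv <- integer(0); pm <- integer(0)
  for (i in seq_along(g3ds)) {
    n <- ns[i]
    if (n < 2L) next
    eg <- expand.grid(u = seq_len(n), v = seq_len(n))
    eg <- eg[eg$u != eg$v, ]
    pu <- c(pu, eg$u + off[i]); pv <- c(pv, eg$v + off[i])
    pm <- c(pm, rep.int(i, nrow(eg)))
  }
  npairs <- length(pu)
  pid <- matrix(0L, n_tot, n_tot)
  if (npairs) pid[cbind(pu, pv)] <- seq_len(npairs)
  tg <- integer(0); tuw <- integer(0); tvw <- integer(0)
  twv <- integer(0); twu <- integer(0)
  for (i in seq_along(g3ds)) {
    nodeset <- seq_len(ns[i]) + off[i]
    local_pairs <- which(pm == i)
    tr <- build_triples(pid, pu[local_pairs], pv[local_pairs], nodeset,
                        mode = "all", null_id = npairs + 1L)
    tg <- c(tg, local_pairs[tr$group])
    tuw <- c(tuw, tr$p_uw); tvw <- c(tvw, tr$p_vw)
    twv <- c(twv, tr$p_wv); twu <- c(twu, tr$p_wu)
  }
  list(n = n_tot, mol_id = mol_id, n_mol = length(g3ds), mol_sizes = ns,
       node_feat = node_feat, coords = coords,
       pairs = list(u = pu, v = pv, mol = pm, n = npairs),
       pid = pid,
       triples = list(group = tg, p_uw = tuw, p_vw = tvw, p_wv = twv, p_wu = twu),
       has_null = FALSE)
}

## ---- parameter registration ------------------------------------------------

init_block_params <- function(ps, prefix, cfg) {
  D_h <- cfg$D_h; D_z <- cfg$D_z
  # node-to-edge
  p_in <- if (cfg$product == "outer") D_h * D_h else D_h
  ps_add_layernorm(ps, paste0(prefix, ".n2e.ln"), D_h)
  ps_add_linear(ps, paste0(prefix, ".n2e.f"), D_h, D_h)
  ps_add_linear(ps, paste0(prefix, ".n2e.out"), p_in, D_z)
  # multiplicative triangle
  ps_add_layernorm(ps, paste0(prefix, ".tm.ln1"), D_z)
  ps_add_layernorm(ps, paste0(prefix, ".tm.ln2"), D_z)
  ps_add_linear(ps, paste0(prefix, ".tm.out"), D_z, D_z)
  ps_add_linear(ps, paste0(prefix, ".tm.gate"), D_z, D_z)
  # attention triangle
  ps_add_linear(ps, paste0(prefix, ".ta.q"), D_z, D_z)
  ps_add_linear(ps, paste0(prefix, ".ta.k"), D_z, D_z)
  ps_add_linear(ps, paste0(prefix, ".ta.v"), D_z, D_z)
  ps_add_linear(ps, paste0(prefix, ".ta.bias"), D_z, cfg$n_heads)
  ps_add_linear(ps, paste0(prefix, ".ta.gate"), D_z, D_z)
  # edge-to-node (two independent 3-layer MLPs)
  ps_add_layernorm(ps, paste0(prefix, ".e2n.ln"), D_z)
  ps_add_mlp(ps, paste0(prefix, ".e2n.row"), c(D_z, cfg$mlp_hidden, cfg$mlp_hidden, D_h))
  ps_add_mlp(ps, paste0(prefix, ".e2n.col"), c(D_z, cfg$mlp_hidden, cfg$mlp_hidden, D_h))
  invisible(ps)
}

init_encoder_params <- function(ps, prefix, cfg, modality, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("init.", prefix)))
  D_h <- cfg$D_h; D_z <- cfg$D_z
  if (modality == "2d") {
    ps_add_linear(ps, paste0(prefix, ".embed"), N_NODE_FEAT, D_h)
    for (l in 1:2) {
      ps_add_linear(ps, paste0(prefix, ".gin", l, ".edge"), N_BOND_FEAT, D_h)
      ps_add_mlp(ps, paste0(prefix, ".gin", l, ".mlp"), c(D_h, D_h, D_h))
    }
    ps_add_linear(ps, paste0(prefix, ".zinit"), D_h, D_z)
    ps_add_linear(ps, paste0(prefix, ".zbond"), N_BOND_FEAT, D_z)
    if (cfg$w2d == "union") {
      ps_add(ps, paste0(prefix, ".znull"), matrix(stats::rnorm(D_z, 0, 0.1), 1L))
    }
  } else {
    ps_add_linear(ps, paste0(prefix, ".embed"), length(ELEMENT_VOCAB), D_h)
    ps_add_linear(ps, paste0(prefix, ".cf.pre"), D_h, D_h)
    ps_add_mlp(ps, paste0(prefix, ".cf.filter"), c(cfg$n_rbf, D_h, D_h))
    ps_add_linear(ps, paste0(prefix, ".cf.post"), D_h, D_h)
    ps_add_linear(ps, paste0(prefix, ".zinit"), cfg$n_rbf, D_z)
  }
  for (b in seq_len(cfg$n_blocks)) {
    init_block_params(ps, paste0(prefix, ".b", b), cfg)
  }
  ps_add_linear(ps, paste0(prefix, ".pool"), D_h, cfg$pool_dim)
  invisible(ps)
}

## ---- forward components (tape-based) ----------------------------------------

fwd_node_to_edge <- function(tape, P, prefix, h, z, pairs, cfg) {
  if (pairs$n == 0L) return(z)
  hn <- nn_layernorm(tape, P, paste0(prefix, ".ln"), h)
  f <- nn_linear(tape, P, paste0(prefix, ".f"), hn)
  fu <- ad_gather_rows(tape, f, pairs$u)
  fv <- ad_gather_rows(tape, f, pairs$v)
  prod <- if (cfg$product == "outer") {
    D <- cfg$D_h
    ad_mul(tape, ad_index_cols(tape, fu, rep(seq_len(D), each = D)),
           ad_index_cols(tape, fv, rep(seq_len(D), times = D)))
  } else {
    ad_mul(tape, fu, fv)
  }
  upd <- nn_linear(tape, P, paste0(prefix, ".out"), prod)
  ad_add(tape, z, upd)
}

# z rows extended with the learned null slot (union mode) or a zero row, so
# triple gathers can address "missing pair" uniformly.
extend_z <- function(tape, P, z, batch, prefix_enc) {
  null_row <- if (batch$has_null) {
    pget(P, paste0(prefix_enc, ".znull"))
  } else {
    matrix(0, 1L, ncol(ad_val(z)))
  }
  ad_concat_rows(tape, list(z, null_row))
}

fwd_triangle_mult <- function(tape, P, prefix, z, batch, enc_prefix) {
  tr <- batch$triples
  npairs <- batch$pairs$n
  if (npairs == 0L || length(tr$group) == 0L) return(z)
  zx <- extend_z(tape, P, z, batch, enc_prefix)
  a <- nn_layernorm(tape, P, paste0(prefix, ".ln1"), zx)
  left <- ad_gather_rows(tape, a, tr$p_uw)
  right <- ad_gather_rows(tape, a, tr$p_vw)
  s <- ad_scatter_sum(tape, ad_mul(tape, left, right), tr$group, npairs)
  mask <- matrix(0, npairs, 1L)
  mask[unique(tr$group), 1L] <- 1
  agg <- nn_layernorm(tape, P, paste0(prefix, ".ln2"), s)
  out <- nn_linear(tape, P, paste0(prefix, ".out"), agg)
  gate <- ad_sigmoid(tape, nn_linear(tape, P, paste0(prefix, ".gate"), z))
  upd <- ad_mul(tape, ad_mul(tape, gate, out),
                matrix(mask, npairs, ncol(ad_val(z))))
  ad_add(tape, z, upd)
}

fwd_triangle_attn <- function(tape, P, prefix, z, batch, cfg, enc_prefix,
                              diag = NULL) {
  tr <- batch$triples
  npairs <- batch$pairs$n
  if (npairs == 0L || length(tr$group) == 0L) return(z)
  H <- cfg$n_heads
  B <- cfg$D_z %/% H
  zx <- extend_z(tape, P, z, batch, enc_prefix)
  q <- nn_linear(tape, P, paste0(prefix, ".q"), z)
  k <- nn_linear(tape, P, paste0(prefix, ".k"), zx)
  v <- nn_linear(tape, P, paste0(prefix, ".v"), zx)
  bias <- nn_linear(tape, P, paste0(prefix, ".bias"), zx)
  qq <- ad_gather_rows(tape, q, tr$group)       # q of the destination pair (u,v)
  kk <- ad_gather_rows(tape, k, tr$p_wv)        # printed pattern: k_{wv}
  dots <- ad_affine(tape, ad_rowsum_blocks(tape, ad_mul(tape, qq, kk), H),
                    mult = 1 / sqrt(B))
  bb <- ad_gather_rows(tape, bias, tr$p_wu)     # printed pattern: b_{wu}
  att <- ad_group_softmax(tape, ad_add(tape, dots, bb), tr$group, npairs)
  if (!is.null(diag)) {
    rs <- dense_rowsum(ad_val(att), tr$group, npairs)
    present <- unique(tr$group)
    diag$attn_dev <- max(diag$attn_dev %||% 0,
                         max(abs(rs[present, , drop = FALSE] - 1)))
  }
  vv <- ad_gather_rows(tape, v, tr$p_uw)        # values from (u,w)
  weighted <- ad_mul(tape, vv, ad_expand_blocks(tape, att, B))
  ctx <- ad_scatter_sum(tape, weighted, tr$group, npairs)
  gate <- ad_sigmoid(tape, nn_linear(tape, P, paste0(prefix, ".gate"), z))
  mask <- matrix(0, npairs, 1L)
  mask[unique(tr$group), 1L] <- 1
  upd <- ad_mul(tape, ad_mul(tape, gate, ctx),
                matrix(mask, npairs, ncol(ad_val(z))))
  ad_add(tape, z, upd)
}

fwd_edge_to_node <- function(tape, P, prefix, h, z, pairs, n_nodes) {
  if (pairs$n == 0L) return(h)
  a <- nn_layernorm(tape, P, paste0(prefix, ".ln"), z)
  agg_out <- ad_scatter_sum(tape, a, pairs$u, n_nodes)  # sum over v in N(u)
  agg_in <- ad_scatter_sum(tape, a, pairs$v, n_nodes)   # sum over u in N(v)
  mask <- matrix(0, n_nodes, 1L)
  mask[unique(c(pairs$u, pairs$v)), 1L] <- 1
  mrow <- nn_mlp(tape, P, paste0(prefix, ".row"), agg_in, 3L)
  mcol <- nn_mlp(tape, P, paste0(prefix, ".col"), agg_out, 3L)
  upd <- ad_mul(tape, ad_add(tape, mrow, mcol),
                matrix(mask, n_nodes, ncol(ad_val(h))))
  ad_add(tape, h, upd)
}

fwd_gin_init <- function(tape, P, prefix, batch, cfg) {
  x <- nn_linear(tape, P, paste0(prefix, ".embed"), batch$node_feat)
  pairs <- batch$pairs
  bond_feat <- featurize_bonds(pairs$type)
  for (l in 1:2) {
    if (pairs$n > 0L) {
      e <- nn_linear(tape, P, paste0(prefix, ".gin", l, ".edge"), bond_feat)
      msg <- ad_relu(tape, ad_add(tape, ad_gather_rows(tape, x, pairs$v), e))
      agg <- ad_scatter_sum(tape, msg, pairs$u, batch$n)
      x <- ad_add(tape, x, agg)
    }
    x <- nn_mlp(tape, P, paste0(prefix, ".gin", l, ".mlp"), x, 2L)
  }
  z <- NULL
  if (pairs$n > 0L) {
    hu <- ad_gather_rows(tape, x, pairs$u)
    hv <- ad_gather_rows(tape, x, pairs$v)
    z <- ad_add(tape, nn_linear(tape, P, paste0(prefix, ".zinit"),
                                ad_add(tape, hu, hv)),
                nn_linear(tape, P, paste0(prefix, ".zbond"), bond_feat))
  } else {
    z <- ad_leaf(NULL, matrix(0, 0L, cfg$D_z))
  }
  list(h = x, z = z)
}

# Radial basis expansion of per-pair distances; `d` may be a tracked node
# (T x 1) so coordinate gradients (e.g. force heads) flow through it.
fwd_rbf <- function(tape, d, cfg) {
  centers <- rbf_centers(cfg)
  gam <- rbf_gamma(cfg)
  dm <- ad_index_cols(tape, d, rep(1L, cfg$n_rbf))
  sh <- ad_add_rowvec(tape, dm, matrix(-centers, 1L))
  ad_exp(tape, ad_affine(tape, ad_square(tape, sh), mult = -gam))
}

# Pair distances from (possibly tracked) coordinates.
fwd_pair_dist <- function(tape, coords, pairs) {
  xu <- ad_gather_rows(tape, coords, pairs$u)
  xv <- ad_gather_rows(tape, coords, pairs$v)
  ad_sqrt(tape, ad_rowsums(tape, ad_square(tape, ad_sub(tape, xu, xv))))
}

fwd_cfconv_init <- function(tape, P, prefix, batch, cfg, coords = NULL) {
  pairs <- batch$pairs
  x <- nn_linear(tape, P, paste0(prefix, ".embed"), batch$node_feat)
  if (pairs$n == 0L) {
    return(list(h = x, z = ad_leaf(NULL, matrix(0, 0L, cfg$D_z)), rbf = NULL))
  }
  if (is.null(coords)) coords <- batch$coords
  d <- fwd_pair_dist(tape, coords, pairs)
  rb <- fwd_rbf(tape, d, cfg)
  filt <- nn_mlp(tape, P, paste0(prefix, ".cf.filter"), rb, 2L)
  pre <- nn_linear(tape, P, paste0(prefix, ".cf.pre"), x)
  msg <- ad_mul(tape, ad_gather_rows(tape, pre, pairs$v), filt)
  agg <- ad_scatter_sum(tape, msg, pairs$u, batch$n)
  h <- ad_add(tape, x, nn_linear(tape, P, paste0(prefix, ".cf.post"), agg))
  z <- nn_linear(tape, P, paste0(prefix, ".zinit"), rb)
  list(h = h, z = z, rbf = rb)
}

fwd_pool <- function(tape, P, prefix, h, batch) {
  s <- ad_scatter_sum(tape, h, batch$mol_id, batch$n_mol)
  m <- ad_mul(tape, s, matrix(1 / batch$mol_sizes, batch$n_mol, ncol(ad_val(h))))
  nn_linear(tape, P, paste0(prefix, ".pool"), m)
}

fwd_encode <- function(tape, P, prefix, batch, cfg, modality,
                       coords = NULL, diag = NULL) {
  st <- if (modality == "2d") {
    fwd_gin_init(tape, P, prefix, batch, cfg)
  } else {
    ini <- fwd_cfconv_init(tape, P, prefix, batch, cfg, coords = coords)
    ini
  }
  h <- st$h; z <- st$z
  for (b in seq_len(cfg$n_blocks)) {
    bp <- paste0(prefix, ".b", b)
    z <- fwd_node_to_edge(tape, P, paste0(bp, ".n2e"), h, z, batch$pairs, cfg)
    z <- fwd_triangle_mult(tape, P, paste0(bp, ".tm"), z, batch, prefix)
    z <- fwd_triangle_attn(tape, P, paste0(bp, ".ta"), z, batch, cfg, prefix,
                           diag = diag)
    h <- fwd_edge_to_node(tape, P, paste0(bp, ".e2n"), h, z, batch$pairs, batch$n)
  }
  pooled <- fwd_pool(tape, P, prefix, h, batch)
  list(h = h, z = z, pooled = pooled)
}

## ---- public encoder interface ----------------------------------------------

as_graph_list <- function(x, field) {
  if (inherits(x, c("Graph2D", "Graph3D"))) return(list(x))
  if (is.list(x) && !is.null(x$g2d)) x <- list(x)
  lapply(x, function(m) {
    if (inherits(m, c("Graph2D", "Graph3D"))) m else m[[field]]
  })
}

#' Initialize encoder parameters
#'
#' Deterministic (Glorot) initialization from a named integer seed. Parameters
#' for both encoders (and optionally the score networks and prediction heads)
#' live in one flat named store so a single optimizer can update everything.
#'
#' @param config an [encoder_config()].
#' @param modality `"2d"`, `"3d"` or `"both"`.
#' @param seed integer seed.
#' @return a parameter store (class `moltri_params`).
#' @export
init_encoder <- function(config = encoder_config(), modality = c("both", "2d", "3d"),
                         seed = 1L) {
  modality <- match.arg(modality)
  ps <- ps_new()
  if (modality %in% c("both", "2d")) init_encoder_params(ps, "enc2d", config, "2d", seed)
  if (modality %in% c("both", "3d")) init_encoder_params(ps, "enc3d", config, "3d", seed)
  attr(ps, "config") <- config
  class(ps) <- "moltri_params"
  ps
}

split_rows <- function(m, sizes) {
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_along(sizes), function(i) m[starts[i]:ends[i], , drop = FALSE])
}

embedding_state <- function(out, batch, diag) {
  pair_sizes <- tabulate(batch$pairs$mol, nbins = batch$n_mol)
  st <- list(h = ad_val(out$h), z = ad_val(out$z),
             pooled = ad_val(out$pooled),
             node_mol = batch$mol_id,
             pairs = data.frame(u = batch$pairs$u, v = batch$pairs$v,
                                mol = batch$pairs$mol),
             h_by_mol = split_rows(ad_val(out$h), batch$mol_sizes),
             attn_rowsum_dev = diag$attn_dev %||% 0)
  class(st) <- "EmbeddingState"
  st
}

#' @export
print.EmbeddingState <- function(x, ...) {
  cat("<EmbeddingState> ", nrow(x$h), " nodes, ", nrow(x$z), " pairs, pooled ",
      nrow(x$pooled), " x ", ncol(x$pooled), "\n", sep = "")
  invisible(x)
}

#' Encode 2D molecular graphs with the triangle-aware 2D encoder
#'
#' Two bond-aware GIN layers initialize node and edge embeddings, followed by
#' `n_blocks` repetitions of node-to-edge, multiplicative triangle, attention
#' triangle and edge-to-node updates over the bonded pair set, then a mean
#' pool over nodes projected to `pool_dim` (default 256).
#'
#' @param graphs a `Graph2D`, a list of them, or a list of paired entries.
#' @param params a `moltri_params` store from [init_encoder()]; created fresh
#'   from `seed` when NULL.
#' @param config an [encoder_config()] (ignored when `params` carries one).
#' @param seed seed for fresh initialization.
#' @return an `EmbeddingState` with node embeddings `h`, ordered-pair
#'   embeddings `z` (with the pair table), and a molecules x 256 `pooled`
#'   matrix.
#' @export
gta2d_encode <- function(graphs, params = NULL, config = encoder_config(),
                         seed = 1L) {
  g2ds <- as_graph_list(graphs, "g2d")
  if (is.null(params)) params <- init_encoder(config, "2d", seed)
  cfg <- attr(params, "config")
  batch <- build_batch2d(g2ds, cfg)
  tape <- ad_tape()
  diag <- new.env(parent = emptyenv())
  out <- fwd_encode(tape, params$val, "enc2d", batch, cfg, "2d", diag = diag)
  embedding_state(out, batch, diag)
}

#' Encode 3D conformations with the triangle-aware 3D encoder
#'
#' One continuous-filter convolution over radial-basis-expanded interatomic
#' distances initializes node embeddings (edge embeddings come from the same
#' expansion), followed by triangle blocks over the fully connected pair set.
#' Output depends on coordinates only through the distance map, so it is
#' invariant to rigid motions by construction.
#'
#' @inheritParams gta2d_encode
#' @export
gta3d_encode <- function(graphs, params = NULL, config = encoder_config(),
                         seed = 1L) {
  g3ds <- as_graph_list(graphs, "g3d")
  if (is.null(params)) params <- init_encoder(config, "3d", seed)
  cfg <- attr(params, "config")
  batch <- build_batch3d(g3ds, cfg)
  tape <- ad_tape()
  diag <- new.env(parent = emptyenv())
  out <- fwd_encode(tape, params$val, "enc3d", batch, cfg, "3d", diag = diag)
  embedding_state(out, batch, diag)
}

#' Run the GIN initialization stage alone
#'
#' @param graph a `Graph2D`.
#' @inheritParams gta2d_encode
#' @return list with node embeddings `h` and bonded-pair embeddings `z`.
#' @export
gin_init_stage <- function(graph, params = NULL, config = encoder_config(),
                           seed = 1L) {
  if (is.null(params)) params <- init_encoder(config, "2d", seed)
  cfg <- attr(params, "config")
  batch <- build_batch2d(list(graph), cfg)
  st <- fwd_gin_init(NULL, params$val, "enc2d", batch, cfg)
  list(h = ad_val(st$h), z = ad_val(st$z),
       pairs = data.frame(u = batch$pairs$u, v = batch$pairs$v))
}

#' Run the continuous-filter convolution initialization stage alone
#'
#' @param graph a `Graph3D`.
#' @inheritParams gta2d_encode
#' @export
cfconv_init_stage <- function(graph, params = NULL, config = encoder_config(),
                              seed = 1L) {
  if (is.null(params)) params <- init_encoder(config, "3d", seed)
  cfg <- attr(params, "config")
  batch <- build_batch3d(list(graph), cfg)
  st <- fwd_cfconv_init(NULL, params$val, "enc3d", batch, cfg)
  list(h = ad_val(st$h), z = ad_val(st$z),
       pairs = data.frame(u = batch$pairs$u, v = batch$pairs$v))
}

## ---- standalone update operations (single graph, explicit parameters) -------

#' Parameters for a standalone triangle-mechanism operation
#'
#' @param op one of `"node_to_edge"`, `"triangle_mult"`, `"triangle_attn"`,
#'   `"edge_to_node"`.
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
triangle_op_params <- function(op = c("node_to_edge", "triangle_mult",
                                      "triangle_attn", "edge_to_node"),
                               config = encoder_config(), seed = 1L) {
  op <- match.arg(op)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("op.", op)))
  ps <- ps_new()
  cfg <- config
  switch(op,
         node_to_edge = {
           p_in <- if (cfg$product == "outer") cfg$D_h^2 else cfg$D_h
           ps_add_layernorm(ps, "ln", cfg$D_h)
           ps_add_linear(ps, "f", cfg$D_h, cfg$D_h)
           ps_add_linear(ps, "out", p_in, cfg$D_z)
         },
         triangle_mult = {
           ps_add_layernorm(ps, "ln1", cfg$D_z)
           ps_add_layernorm(ps, "ln2", cfg$D_z)
           ps_add_linear(ps, "out", cfg$D_z, cfg$D_z)
           ps_add_linear(ps, "gate", cfg$D_z, cfg$D_z)
         },
         triangle_attn = {
           ps_add_linear(ps, "q", cfg$D_z, cfg$D_z)
           ps_add_linear(ps, "k", cfg$D_z, cfg$D_z)
           ps_add_linear(ps, "v", cfg$D_z, cfg$D_z)
           ps_add_linear(ps, "bias", cfg$D_z, cfg$n_heads)
           ps_add_linear(ps, "gate", cfg$D_z, cfg$D_z)
         },
         edge_to_node = {
           ps_add_layernorm(ps, "ln", cfg$D_z)
           ps_add_mlp(ps, "row", c(cfg$D_z, cfg$mlp_hidden, cfg$mlp_hidden, cfg$D_h))
           ps_add_mlp(ps, "col", c(cfg$D_z, cfg$mlp_hidden, cfg$mlp_hidden, cfg$D_h))
         })
  ps$val
}

single_graph_batch <- function(graph, cfg) {
  if (inherits(graph, "Graph2D")) build_batch2d(list(graph), cfg)
  else build_batch3d(list(graph), cfg)
}

check_widths <- function(m, expected, what) {
  if (ncol(m) != expected) {
    stop(what, " width mismatch: expected ", expected, ", got ", ncol(m))
  }
}

#' Node-to-edge update (standalone)
#'
#' Residual update `z_uv <- z_uv + Linear(f(h_u) * f(h_v))` with
#' `f = Linear(LayerNorm(.))`; the product is elementwise (commutative) by
#' default so symmetric inputs stay symmetric. Zeroing the update path leaves
#' `z` unchanged.
#'
#' @param h node embedding matrix (n x D_h).
#' @param z ordered-pair embedding matrix (pairs x D_z), pairs enumerated as in
#'   the graph's modality (bonded for 2D, all ordered pairs for 3D).
#' @param graph a `Graph2D` or `Graph3D`.
#' @param params named parameter list from [triangle_op_params()].
#' @param config an [encoder_config()] matching the widths.
#' @return updated `z`.
#' @export
node_to_edge <- function(h, z, graph, params, config = encoder_config()) {
  check_widths(h, config$D_h, "node embedding")
  check_widths(z, config$D_z, "edge embedding")
  batch <- single_graph_batch(graph, config)
  stopifnot(nrow(z) == batch$pairs$n, nrow(h) == batch$n)
  p <- stats::setNames(params, paste0("op.", names(params)))
  ad_val(fwd_node_to_edge(NULL, p, "op", h, z, batch$pairs, config))
}

#' Multiplicative triangle update (standalone)
#'
#' For each pair (u,v), sums `LayerNorm(z_uw) * LayerNorm(z_vw)` over the
#' admissible third vertices w, re-normalizes, projects, and adds the result
#' residually under a sigmoid gate computed from `z_uv`. Pairs with no
#' admissible w are left unchanged.
#'
#' @inheritParams node_to_edge
#' @export
triangle_mult_update <- function(z, graph, params, config = encoder_config()) {
  check_widths(z, config$D_z, "edge embedding")
  batch <- single_graph_batch(graph, config)
  stopifnot(nrow(z) == batch$pairs$n)
  p <- stats::setNames(params, paste0("op.", names(params)))
  ad_val(fwd_triangle_mult(NULL, p, "op", z, batch, "enc"))
}

#' Attention triangle update (standalone)
#'
#' Per head, attention weights over admissible third vertices w use the
#' printed index pattern `a_uvw = softmax_w(q_uv . k_wv / c + b_wu)` with
#' `c = sqrt(per-head width)`; the update adds `gate * sum_w a_uvw v_uw`
#' residually. With one head this is exactly the printed single-head form.
#'
#' @inheritParams node_to_edge
#' @return updated `z`; attribute `"attn_rowsum_dev"` holds the maximum
#'   deviation of any attention row sum from 1.
#' @export
triangle_attn_update <- function(z, graph, params, config = encoder_config()) {
  check_widths(z, config$D_z, "edge embedding")
  batch <- single_graph_batch(graph, config)
  stopifnot(nrow(z) == batch$pairs$n)
  diag <- new.env(parent = emptyenv())
  p <- stats::setNames(params, paste0("op.", names(params)))
  out <- ad_val(fwd_triangle_attn(NULL, p, "op", z, batch, config, "enc",
                                  diag = diag))
  attr(out, "attn_rowsum_dev") <- diag$attn_dev %||% 0
  out
}

#' Edge-to-node update (standalone)
#'
#' Aggregates LayerNormed pair embeddings separately along rows and columns of
#' the pair array (incoming and outgoing ordered pairs) through two
#' independent 3-layer MLPs, added residually. Isolated nodes are unchanged.
#'
#' @inheritParams node_to_edge
#' @return updated `h`.
#' @export
edge_to_node <- function(h, z, graph, params, config = encoder_config()) {
  check_widths(h, config$D_h, "node embedding")
  check_widths(z, config$D_z, "edge embedding")
  batch <- single_graph_batch(graph, config)
  stopifnot(nrow(z) == batch$pairs$n, nrow(h) == batch$n)
  p <- stats::setNames(params, paste0("op.", names(params)))
  ad_val(fwd_edge_to_node(NULL, p, "op", h, z, batch$pairs, batch$n))
}
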
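# Naive per-pair / per-triple loop references for the four update operations.
# Written independently of the package internals: plain double/triple loops
# over explicit index sets, using only the parameter matrices.

ref_layernorm <- function(x, g, s, eps = 1e-5) {
  t(apply(x, 1L, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * as.numeric(g) + as.numeric(s)
  }))
}

ref_linear <- function(x, W, b) sweep(x %*% W, 2L, as.numeric(b), "+")

ref_mlp3 <- function(x, p, prefix) {
  h <- pmax(ref_linear(x, p[[paste0(prefix, ".l1.W")]], p[[paste0(prefix, ".l1.b")]]), 0)
  h <- pmax(ref_linear(h, p[[paste0(prefix, ".l2.W")]], p[[paste0(prefix, ".l2.b")]]), 0)
  ref_linear(h, p[[paste0(prefix, ".l3.W")]], p[[paste0(prefix, ".l3.b")]])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Ordered pair enumeration matching the package convention: bonded directed
# pairs for Graph2D (both directions, bond list order), all ordered pairs for
# Graph3D (expand.grid order, u varying fastest, u != v).
ref_pairs <- function(graph) {
  if (inherits(graph, "Graph2D")) {
    data.frame(u = graph$bond_u, v = graph$bond_v)
  } else {
    eg <- expand.grid(u = seq_len(graph$n), v = seq_len(graph$n))
    eg[eg$u != eg$v, c("u", "v")]
  }
}

# Admissible third-vertex set: N(u) & N(v) for 2D, all other nodes for 3D.
ref_wset <- function(graph, u, v) {
  if (inherits(graph, "Graph2D")) {
    nu <- graph$bond_v[graph$bond_u == u]
    nv <- graph$bond_v[graph$bond_u == v]
    setdiff(intersect(nu, nv), c(u, v))
  } else {
    setdiff(seq_len(graph$n), c(u, v))
  }
}

pair_id <- function(pairs, u, v) which(pairs$u == u & pairs$v == v)

ref_node_to_edge <- function(h, z, graph, p) {
  pairs <- ref_pairs(graph)
  f <- ref_linear(ref_layernorm(h, p[["ln.g"]], p[["ln.s"]]),
                  p[["f.W"]], p[["f.b"]])
  out <- z
  for (i in seq_len(nrow(pairs))) {
    prod <- f[pairs$u[i], ] * f[pairs$v[i], ]
    out[i, ] <- z[i, ] + as.numeric(ref_linear(matrix(prod, 1L),
                                               p[["out.W"]], p[["out.b"]]))
  }
  out
}

ref_triangle_mult <- function(z, graph, p) {
  pairs <- ref_pairs(graph)
  a <- ref_layernorm(z, p[["ln1.g"]], p[["ln1.s"]])
  out <- z
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$u[i]; v <- pairs$v[i]
    W <- ref_wset(graph, u, v)
    if (length(W) == 0L) next
    s <- 0
    for (w in W) s <- s + a[pair_id(pairs, u, w), ] * a[pair_id(pairs, v, w), ]
    agg <- ref_layernorm(matrix(s, 1L), p[["ln2.g"]], p[["ln2.s"]])
    upd <- ref_linear(agg, p[["out.W"]], p[["out.b"]])
    gate <- sigmoid(ref_linear(matrix(z[i, ], 1L), p[["gate.W"]], p[["gate.b"]]))
    out[i, ] <- z[i, ] + as.numeric(gate) * as.numeric(upd)
  }
  out
}

ref_triangle_attn <- function(z, graph, p, n_heads) {
  pairs <- ref_pairs(graph)
  D <- ncol(z); B <- D %/% n_heads
  q <- ref_linear(z, p[["q.W"]], p[["q.b"]])
  k <- ref_linear(z, p[["k.W"]], p[["k.b"]])
  v <- ref_linear(z, p[["v.W"]], p[["v.b"]])
  bb <- ref_linear(z, p[["bias.W"]], p[["bias.b"]])
  out <- z
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$u[i]; vv_ <- pairs$v[i]
    W <- ref_wset(graph, u, vv_)
    if (length(W) == 0L) next
    # scores use the printed pattern (q_uv . k_wv, bias b_wu); values are v_uw
    ctx <- numeric(D)
    for (hh in seq_len(n_heads)) {
      cols <- ((hh - 1L) * B + 1L):(hh * B)
      logits <- vapply(W, function(w) {
        sum(q[i, cols] * k[pair_id(pairs, w, vv_), cols]) / sqrt(B) +
          bb[pair_id(pairs, w, u), hh]
      }, 0)
      aw <- exp(logits - max(logits)); aw <- aw / sum(aw)
      for (j in seq_along(W)) {
        ctx[cols] <- ctx[cols] + aw[j] * v[pair_id(pairs, u, W[j]), cols]
      }
    }
    gate <- sigmoid(ref_linear(matrix(z[i, ], 1L), p[["gate.W"]], p[["gate.b"]]))
    out[i, ] <- z[i, ] + as.numeric(gate) * ctx
  }
  out
}

ref_edge_to_node <- function(h, z, graph, p) {
  pairs <- ref_pairs(graph)
  a <- ref_layernorm(z, p[["ln.g"]], p[["ln.s"]])
  out <- h
  for (u in seq_len(nrow(h))) {
    outgoing <- which(pairs$u == u)
    incoming <- which(pairs$v == u)
    if (length(outgoing) + length(incoming) == 0L) next
    s_in <- colSums(a[incoming, , drop = FALSE])
    s_out <- colSums(a[outgoing, , drop = FALSE])
    upd <- ref_mlp3(matrix(s_in, 1L), p, "row") + ref_mlp3(matrix(s_out, 1L), p, "col")
    out[u, ] <- h[u, ] + as.numeric(upd)
  }
  out
}

# Independent cfconv reference: one continuous-filter convolution.
ref_cfconv <- function(graph, p, cfg) {
  n <- graph$n
  el <- moltri:::element_from_z(graph$z)
  vocab <- moltri:::ELEMENT_VOCAB
  X <- matrix(0, n, length(vocab))
  X[cbind(seq_len(n), match(el, vocab, nomatch = length(vocab)))] <- 1
  x <- ref_linear(X, p[["enc3d.embed.W"]], p[["enc3d.embed.b"]])
  centers <- seq(0, cfg$rbf_max, length.out = cfg$n_rbf)
  spacing <- cfg$rbf_max / (cfg$n_rbf - 1L)
  gam <- 1 / (2 * spacing^2)
  pre <- ref_linear(x, p[["enc3d.cf.pre.W"]], p[["enc3d.cf.pre.b"]])
  h <- x
  for (u in seq_len(n)) {
    acc <- 0
    for (v in setdiff(seq_len(n), u)) {
      rb <- exp(-gam * (graph$dist[u, v] - centers)^2)
      filt <- pmax(ref_linear(matrix(rb, 1L), p[["enc3d.cf.filter.l1.W"]],
                              p[["enc3d.cf.filter.l1.b"]]), 0)
      filt <- ref_linear(filt, p[["enc3d.cf.filter.l2.W"]],
                         p[["enc3d.cf.filter.l2.b"]])
      acc <- acc + pre[v, ] * as.numeric(filt)
    }
    h[u, ] <- x[u, ] + as.numeric(ref_linear(matrix(acc, 1L),
                                             p[["enc3d.cf.post.W"]],
                                             p[["enc3d.cf.post.b"]]))
  }
  h
}
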
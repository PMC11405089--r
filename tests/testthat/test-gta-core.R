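# Triangle-mechanism operations against naive loop oracles, residual/identity
# contracts, and encoder-level symmetry properties.

test_that("all four update operations match brute-force loop references", {
  set.seed(101)
  cfg <- test_cfg(D = 8L, heads = 2L)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    graph <- if (rep %% 2 == 0) random_graph2d(n) else random_graph3d(n)
    npairs <- if (inherits(graph, "Graph2D")) length(graph$bond_u) else n * (n - 1L)
    h <- matrix(rnorm(n * cfg$D_h), n)
    z <- matrix(rnorm(npairs * cfg$D_z), npairs)

    p <- triangle_op_params("node_to_edge", cfg, seed = rep)
    expect_lt(max(abs(node_to_edge(h, z, graph, p, cfg) -
                        ref_node_to_edge(h, z, graph, p))), 1e-5)

    p <- triangle_op_params("triangle_mult", cfg, seed = rep)
    expect_lt(max(abs(triangle_mult_update(z, graph, p, cfg) -
                        ref_triangle_mult(z, graph, p))), 1e-5)

    p <- triangle_op_params("triangle_attn", cfg, seed = rep)
    got <- triangle_attn_update(z, graph, p, cfg)
    expect_lt(max(abs(got - ref_triangle_attn(z, graph, p, cfg$n_heads))), 1e-5)
    expect_lt(attr(got, "attn_rowsum_dev"), 1e-6)

    p <- triangle_op_params("edge_to_node", cfg, seed = rep)
    expect_lt(max(abs(edge_to_node(h, z, graph, p, cfg) -
                        ref_edge_to_node(h, z, graph, p))), 1e-5)
  }
})

test_that("single-head attention reproduces the printed single-head form", {
  set.seed(5)
  cfg1 <- test_cfg(D = 8L, heads = 1L)
  g <- random_graph3d(5)
  z <- matrix(rnorm(20 * 8), 20)
  p <- triangle_op_params("triangle_attn", cfg1, seed = 2)
  expect_lt(max(abs(triangle_attn_update(z, g, p, cfg1) -
                      ref_triangle_attn(z, g, p, 1L))), 1e-5)
})

test_that("node_to_edge is residual and commutative in the node pair", {
  set.seed(11)
  cfg <- test_cfg(D = 8L)
  eth <- ethanol_entry()$g2d
  h <- matrix(rnorm(3 * 8), 3)
  z <- matrix(rnorm(4 * 8), 4)
  p <- triangle_op_params("node_to_edge", cfg, seed = 1)
  p[["out.W"]][] <- 0; p[["out.b"]][] <- 0
  expect_identical(node_to_edge(h, z, eth, p, cfg), z)  # residual identity
  # symmetric inputs stay symmetric under the elementwise product
  p <- triangle_op_params("node_to_edge", cfg, seed = 2)
  h[2, ] <- h[1, ]       # h_u = h_v for the (1,2) bond
  z[3, ] <- z[1, ]       # directed rows: 1 = (1,2), 3 = (2,1)
  out <- node_to_edge(h, z, eth, p, cfg)
  expect_equal(out[1, ], out[3, ], tolerance = 1e-12)
  expect_error(node_to_edge(h[, 1:4], z, eth, p, cfg), "width mismatch")
})

test_that("triangle updates leave pairs with an empty third-vertex set unchanged", {
  cfg <- test_cfg(D = 8L)
  eth <- ethanol_entry()$g2d  # path graph: no shared neighbors
  z <- matrix(rnorm(4 * 8), 4)
  pm <- triangle_op_params("triangle_mult", cfg, seed = 3)
  expect_identical(triangle_mult_update(z, eth, pm, cfg), z)
  pa <- triangle_op_params("triangle_attn", cfg, seed = 3)
  out <- triangle_attn_update(z, eth, pa, cfg)
  expect_equal(unclass(out), z, ignore_attr = TRUE)
})

test_that("a saturated-negative gate suppresses the multiplicative update", {
  set.seed(21)
  cfg <- test_cfg(D = 8L)
  g <- random_graph3d(5)
  z <- matrix(rnorm(20 * 8), 20)
  p <- triangle_op_params("triangle_mult", cfg, seed = 4)
  p[["gate.W"]][] <- 0; p[["gate.b"]][] <- -50
  expect_lt(max(abs(triangle_mult_update(z, g, p, cfg) - z)), 1e-4)
})

test_that("degenerate attention cases: one admissible w, and uniform ties", {
  set.seed(31)
  cfg <- test_cfg(D = 8L, heads = 2L)
  tri <- triring_entry()$g2d  # each bonded pair has exactly one shared neighbor
  z <- matrix(rnorm(6 * 8), 6)
  p <- triangle_op_params("triangle_attn", cfg, seed = 5)
  out <- triangle_attn_update(z, tri, p, cfg)
  # softmax over a single w is 1: update is gate * v_uw exactly
  pairs <- ref_pairs(tri)
  vmat <- ref_linear(z, p[["v.W"]], p[["v.b"]])
  i <- 1L  # pair (1,2); the only admissible w is 3
  gate <- sigmoid(ref_linear(matrix(z[i, ], 1L), p[["gate.W"]], p[["gate.b"]]))
  expected <- z[i, ] + as.numeric(gate) * vmat[pair_id(pairs, 1L, 3L), ]
  expect_lt(max(abs(out[i, ] - expected)), 1e-8)
  # identical rows of z make all k, b, v coincide: weights tie at 1/|W|
  g3 <- random_graph3d(4)
  z_eq <- matrix(rep(rnorm(8), each = 12), 12)
  out3 <- triangle_attn_update(z_eq, g3, p, cfg)
  vrow <- ref_linear(z_eq[1, , drop = FALSE], p[["v.W"]], p[["v.b"]])
  g1 <- sigmoid(ref_linear(z_eq[1, , drop = FALSE], p[["gate.W"]], p[["gate.b"]]))
  expect_lt(max(abs(out3[1, ] - (z_eq[1, ] + as.numeric(g1) * as.numeric(vrow)))), 1e-8)
})

test_that("edge_to_node leaves isolated nodes unchanged", {
  cfg <- test_cfg(D = 8L)
  g <- graph2d(c("C", "C", "O"), data.frame(u = 1, v = 2, type = 1L))
  h <- matrix(rnorm(3 * 8), 3)
  z <- matrix(rnorm(2 * 8), 2)
  p <- triangle_op_params("edge_to_node", cfg, seed = 6)
  out <- edge_to_node(h, z, g, p, cfg)
  expect_identical(out[3, ], h[3, ])    # atom 3 has no incident pairs
  expect_false(isTRUE(all.equal(out[1, ], h[1, ])))
})

test_that("GIN init stage is permutation-equivariant and two-hop sensitive", {
  cfg <- test_cfg(D = 8L)
  params <- init_encoder(cfg, "2d", seed = 9L)
  g <- random_graph2d(6)
  st <- gin_init_stage(g, params = params)
  pi <- sample.int(6)
  stp <- gin_init_stage(moltri:::permute_graph2d(g, pi), params = params)
  expect_lt(max(abs(stp$h[pi, ] - st$h)), 1e-10)
  # path vs triangle with identical atom types differ (two-hop information)
  path <- graph2d(rep("C", 3), data.frame(u = c(1, 2), v = c(2, 3), type = 1L))
  tri <- triring_entry()$g2d
  hp <- gin_init_stage(path, params = params)$h
  ht <- gin_init_stage(tri, params = params)$h
  expect_gt(max(abs(hp[2, ] - ht[2, ])), 1e-6)
  # single-node molecule: embedding defined, empty edge set
  single <- gin_init_stage(graph2d("O"), params = params)
  expect_equal(dim(single$h), c(1L, 8L))
  expect_equal(nrow(single$z), 0L)
  # unknown element maps to the 'other' bucket with a warning
  expect_warning(gin_init_stage(graph2d(c("Xx", "C"),
                                        data.frame(u = 1, v = 2, type = 1L)),
                                params = params),
                 "other")
})

test_that("cfconv init depends on coordinates only through distances", {
  cfg <- test_cfg(D = 8L)
  params <- init_encoder(cfg, "3d", seed = 9L)
  set.seed(2)
  g <- random_graph3d(5)
  st <- cfconv_init_stage(g, params = params)
  rot <- moltri:::rigid_motion(g$coords)
  st2 <- cfconv_init_stage(build_graph3d(rot, g$z), params = params)
  expect_lt(max(abs(st2$h - st$h)), 1e-5)
  expect_lt(max(abs(st2$z - st$z)), 1e-5)
  # moving two atoms apart changes the pair embedding (radial basis responds)
  a <- build_graph3d(rbind(c(0, 0, 0), c(1.5, 0, 0)), c(6L, 6L))
  b <- build_graph3d(rbind(c(0, 0, 0), c(3.0, 0, 0)), c(6L, 6L))
  za <- cfconv_init_stage(a, params = params)$z
  zb <- cfconv_init_stage(b, params = params)$z
  expect_gt(max(abs(za - zb)), 1e-4)
  # loop oracle for the convolution sum
  expect_lt(max(abs(st$h - ref_cfconv(g, params$val, cfg))), 1e-5)
})

test_that("encoders pool to width 256 and are permutation-symmetric", {
  cfg <- test_cfg(D = 8L)
  fx <- small_fixtures()[1:4]
  st2 <- gta2d_encode(fx, config = cfg, seed = 2L)
  st3 <- gta3d_encode(fx, config = cfg, seed = 2L)
  expect_equal(ncol(st2$pooled), 256L)
  expect_equal(ncol(st3$pooled), 256L)
  params2 <- init_encoder(cfg, "2d", seed = 12L)
  params3 <- init_encoder(cfg, "3d", seed = 12L)
  for (rep in 1:50) {
    m <- fx[[(rep %% 4) + 1L]]
    pi <- sample.int(m$g2d$n)
    a <- gta2d_encode(m$g2d, params = params2)
    b <- gta2d_encode(moltri:::permute_graph2d(m$g2d, pi), params = params2)
    expect_lt(max(abs(b$h[pi, , drop = FALSE] - a$h)), 1e-5)
    expect_lt(max(abs(b$pooled - a$pooled)), 1e-5)
    a3 <- gta3d_encode(m$g3d, params = params3)
    b3 <- gta3d_encode(moltri:::permute_graph3d(m$g3d, pi), params = params3)
    expect_lt(max(abs(b3$h[pi, , drop = FALSE] - a3$h)), 1e-5)
    expect_lt(max(abs(b3$pooled - a3$pooled)), 1e-5)
  }
})

test_that("batched forward equals the concatenation of single-molecule forwards", {
  cfg <- test_cfg(D = 8L)
  fx <- make_fixture_set(fixture_spec(n_molecules = 10L, n_atoms = c(3L, 8L),
                                      seed = 23L))
  params2 <- init_encoder(cfg, "2d", seed = 4L)
  params3 <- init_encoder(cfg, "3d", seed = 4L)
  big2 <- gta2d_encode(fx, params = params2)
  big3 <- gta3d_encode(fx, params = params3)
  for (i in seq_along(fx)) {
    one2 <- gta2d_encode(fx[[i]]$g2d, params = params2)
    expect_lt(max(abs(big2$h_by_mol[[i]] - one2$h)), 1e-5)
    expect_lt(max(abs(big2$pooled[i, ] - one2$pooled)), 1e-5)
    one3 <- gta3d_encode(fx[[i]]$g3d, params = params3)
    expect_lt(max(abs(big3$pooled[i, ] - one3$pooled)), 1e-5)
  }
})

test_that("every trainable parameter gets a defined finite gradient from the combined loss", {
  cfg <- test_cfg(D = 8L)
  # include a 3-ring so the 2D triangle stage is active
  batch <- c(small_fixtures()[1:3], list(triring_entry()))
  m <- moltri_model(config = cfg, seed = 8L)
  tape <- moltri:::ad_tape()
  P <- moltri:::ps_leaves(tape, m$ps)
  out <- moltri:::fwd_loss_bundle(tape, P, m, batch, seed = 3L)
  moltri:::ad_backward(tape, out$total)
  g <- moltri:::ps_grads(m$ps, P)
  expect_equal(length(g), length(m$ps$val))
  expect_true(all(vapply(g, function(x) all(is.finite(x)), TRUE)))
  # the 2D triangle parameters participate when triangles exist
  expect_true(any(g[["enc2d.b1.tm.out.W"]] != 0))
  expect_true(any(g[["enc2d.b1.ta.v.W"]] != 0))
})

test_that("union-mode 2D triangles use the learned null for missing pairs", {
  cfgU <- encoder_config(D_h = 8L, D_z = 8L, n_blocks = 1L, n_heads = 2L,
                         mlp_hidden = 8L, pool_dim = 256L, w2d = "union")
  eth <- ethanol_entry()$g2d
  st <- gta2d_encode(eth, config = cfgU, seed = 2L)
  # path graph under union mode has non-empty W, so z changes relative to
  # the intersection-mode encoder after the init stage
  cfgI <- test_cfg(D = 8L)
  expect_false(isTRUE(all.equal(st$z,
                                gta2d_encode(eth, config = cfgI, seed = 2L)$z)))
  expect_true(all(is.finite(st$z)))
})
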
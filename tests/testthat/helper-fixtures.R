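# Shared fixtures, small configurations, and memoized training runs (the
# expensive demonstrations are computed once per test session and asserted
# from several files).

test_cfg <- function(D = 8L, blocks = 1L, heads = 2L) {
  encoder_config(D_h = D, D_z = D, n_blocks = blocks, n_heads = heads,
                 mlp_hidden = D, pool_dim = 256L)
}

# A paired entry for a hand-built molecule.
pair_entry <- function(elements, bonds, coords, name = "toy") {
  g2d <- graph2d(elements, bonds)
  list(g2d = g2d,
       g3d = build_graph3d(coords, as.integer(moltri:::ELEMENT_Z[elements])),
       name = name)
}

ethanol_entry <- function() {
  pair_entry(c("C", "C", "O"),
             data.frame(u = c(1, 2), v = c(2, 3), type = c(1L, 1L)),
             rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.0, 1.3, 0)),
             name = "ethanol")
}

benzene_entry <- function() {
  ang <- 2 * pi * (0:5) / 6
  R <- 1.39 / (2 * sin(pi / 6))
  pair_entry(rep("C", 6),
             data.frame(u = 1:6, v = c(2:6, 1), type = 4L),
             cbind(R * cos(ang), R * sin(ang), 0),
             name = "benzene")
}

# Cyclopropane-like 3-ring: the smallest 2D graph with bonded triangles.
triring_entry <- function() {
  s <- 1.54
  pair_entry(c("C", "C", "C"),
             data.frame(u = c(1, 2, 3), v = c(2, 3, 1), type = 1L),
             rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0)),
             name = "triring")
}

small_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_set(
      fixture_spec(n_molecules = 10L, n_atoms = c(3L, 8L), seed = 7L))
    cache
  }
})

# Random Graph2D with arbitrary topology (may include triangles), for the
# brute-force oracle comparisons.
random_graph2d <- function(n, p_edge = 0.5) {
  repeat {
    adj <- matrix(stats::runif(n * n) < p_edge, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    eg <- which(adj, arr.ind = TRUE)
    if (nrow(eg) >= 1L) break
  }
  graph2d(sample(c("C", "N", "O"), n, replace = TRUE),
          data.frame(u = eg[, 1], v = eg[, 2],
                     type = sample(1:4, nrow(eg), replace = TRUE)))
}

random_graph3d <- function(n) {
  build_graph3d(matrix(stats::rnorm(n * 3, 0, 2), n), sample(c(6L, 7L, 8L), n, TRUE))
}

## ---- memoized expensive runs -------------------------------------------------

.moltri_cache <- new.env(parent = emptyenv())

# The cross-modal edge-information-transfer demonstration: 300 edge-objective
# steps on the fixture set, probed on held-out fixtures.
edge_transfer_run <- function() {
  if (is.null(.moltri_cache$edge)) {
    train <- make_fixture_set(fixture_spec(n_molecules = 40L, seed = 11L))
    heldout <- make_fixture_set(fixture_spec(n_molecules = 15L, seed = 99L))
    cfg <- encoder_config(D_h = 16L, D_z = 16L, n_blocks = 1L, n_heads = 2L,
                          mlp_hidden = 16L, pool_dim = 256L)
    m0 <- moltri_model(config = cfg, seed = 5L)
    probe0 <- edge_probe_accuracy(heldout, m0)
    m <- train_edge_objectives(train, model = m0, steps = 300L, lr = 3e-3,
                               seed = 1L)
    .moltri_cache$edge <- list(model = m, untrained = probe0,
                               trained = edge_probe_accuracy(heldout, m),
                               heldout = heldout)
  }
  .moltri_cache$edge
}

# The end-to-end overfit run: 200 pretraining steps on 8 fixture molecules.
overfit_run <- function() {
  if (is.null(.moltri_cache$overfit)) {
    fx <- make_fixture_set(fixture_spec(n_molecules = 8L, n_atoms = c(3L, 8L),
                                        seed = 7L))
    m <- moltri_model(config = test_cfg(), seed = 5L)
    m <- pretrain(fx, model = m, steps = 200L, batch_size = 8L, lr = 1e-3,
                  seed = 1L)
    .moltri_cache$overfit <- list(model = m, history = attr(m, "history"),
                                  mols = fx)
  }
  .moltri_cache$overfit
}

# Finetune overfit on separable ring-presence labels (train = test).
finetune_overfit_run <- function() {
  if (is.null(.moltri_cache$ft)) {
    fx <- make_fixture_set(fixture_spec(n_molecules = 24L, seed = 21L))
    lab <- make_property_labels(fx, "classification")
    keep <- c(which(lab$label == 1)[1:8], which(lab$label == 0)[1:8])
    mols <- fx[keep]; y <- lab$label[keep]
    model <- moltri_model(config = test_cfg(), seed = 3L)
    fit <- finetune(mols, y, list(train = 1:16, test = 1:16), model,
                    task = "classification", epochs = 150L, lr = 1e-2,
                    seed = 1L)
    .moltri_cache$ft <- list(fit = fit, labels = y)
  }
  .moltri_cache$ft
}
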
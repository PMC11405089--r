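# Edge supervision, node contrastive and InfoNCE objectives, and the
# weighted total.

zero_head <- function(model, prefix) {
  for (nm in grep(paste0("^", prefix), names(model$ps$val), value = TRUE)) {
    model$ps$val[[nm]][] <- 0
  }
  model
}

test_that("uniform predictions give the closed-form cross-entropies", {
  cfg <- test_cfg(D = 8L)
  model <- zero_head(moltri_model(config = cfg, seed = 2L), "head\\.")
  mols <- small_fixtures()[1:3]
  expect_equal(edge_loss_2d(mols, model), log(32), tolerance = 1e-6)
  expect_equal(edge_loss_2d(mols, model, bonded_only = TRUE), log(32),
               tolerance = 1e-6)
  expect_equal(edge_loss_3d(mols, model), log(5), tolerance = 1e-6)
  # the literal summed form scales by the pair count
  npairs <- sum(vapply(mols, function(m) m$g2d$n * (m$g2d$n - 1) / 2, 0))
  expect_equal(edge_loss_3d(mols, model, reduce = "sum"), npairs * log(5),
               tolerance = 1e-4)
})

test_that("cross-entropy matches hand-computed values and is zero when perfect", {
  # 2-pair toy with hand-set logits
  logits <- rbind(c(2, 0.5, -1), c(-0.3, 0.1, 1.2))
  labels <- c(1L, 3L)
  byhand <- mean(c(-log(exp(2) / sum(exp(c(2, 0.5, -1)))),
                   -log(exp(1.2) / sum(exp(c(-0.3, 0.1, 1.2))))))
  expect_equal(softmax_cross_entropy(logits, labels), byhand, tolerance = 1e-6)
  # ethanol: 2 single-bond pairs + 1 no-bond pair, hand-set 5-class logits
  eth <- ethanol_entry()
  lab <- bond_labels(eth$g2d)
  labs <- lab[upper.tri(lab)]
  lg <- matrix(rep(c(0.7, -0.2, 0.1, 0.4, 1.1), each = 3), 3L)
  byhand2 <- mean(vapply(seq_len(3), function(i) {
    -log(exp(lg[i, labs[i]]) / sum(exp(lg[i, ])))
  }, 0))
  expect_equal(softmax_cross_entropy(lg, labs), byhand2, tolerance = 1e-6)
  # perfect (near-one-hot) predictions drive the loss to zero
  perfect <- matrix(-1e4, 3L, 5L)
  perfect[cbind(1:3, labs)] <- 1e4
  expect_equal(softmax_cross_entropy(perfect, labs), 0)
  expect_gte(softmax_cross_entropy(lg, labs), 0)
})

test_that("edge losses reject unpaired or mismatched molecules", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  eth <- ethanol_entry(); benz <- benzene_entry()
  bad <- list(list(g2d = eth$g2d, g3d = benz$g3d))
  expect_error(edge_loss_2d(bad, model), "mismatch")
  expect_error(edge_loss_3d(bad, model), "mismatch")
  expect_error(edge_loss_2d(list(list(g2d = eth$g2d, g3d = NULL)), model),
               "paired conformation")
})

test_that("zero discriminators give log 2 per modality term", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  for (nm in c("score23.disc.W", "score23.disc.b",
               "score32.disc.W", "score32.disc.b")) {
    model$ps$val[[nm]][] <- 0
  }
  mols <- small_fixtures()[1:3]
  l <- node_contrastive_loss(mols, model, seed = 4L)
  expect_equal(attr(l, "l2d"), log(2), tolerance = 1e-9)
  expect_equal(attr(l, "l3d"), log(2), tolerance = 1e-9)
  expect_equal(as.numeric(l), 2 * log(2), tolerance = 1e-9)
  expect_error(node_contrastive_loss(mols[1], model), "at least 2")
})

test_that("constant discriminator bias reproduces the hand-computed EBM-NCE value", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  cval <- 1.3
  for (nm in c("score23.disc.W", "score32.disc.W")) model$ps$val[[nm]][] <- 0
  model$ps$val[["score23.disc.b"]][] <- cval
  model$ps$val[["score32.disc.b"]][] <- cval
  mols <- small_fixtures()[1:4]
  l <- node_contrastive_loss(mols, model, seed = 4L)
  sp <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
  byhand <- 0.5 * (sp(-cval) + sp(cval))  # -1/2 log sig(c) - 1/2 log(1-sig(c))
  expect_equal(attr(l, "l2d"), byhand, tolerance = 1e-9)
  expect_equal(attr(l, "l3d"), byhand, tolerance = 1e-9)
})

test_that("InfoNCE closed forms: uniform similarities and dominant diagonal", {
  K <- 5L
  same <- matrix(rep(rnorm(16), each = K), K)  # identical rows: all sims equal
  expect_equal(gta_infomax_loss(same, same + 0 * same), log(K), tolerance = 1e-9)
  # orthogonal paired embeddings: diagonal cosine 1, off-diagonal 0
  eye <- diag(1, 4L)
  expect_lt(gta_infomax_loss(eye, eye, temperature = 0.02), 1e-6)
  expect_error(gta_infomax_loss(eye[1, , drop = FALSE], eye[1, , drop = FALSE]),
               "at least 2")
})

test_that("InfoNCE matches a hand-computed batch-of-3 similarity matrix", {
  # unit vectors with known pairwise cosines
  p2 <- rbind(c(1, 0), c(0, 1), c(sqrt(0.5), sqrt(0.5)))
  p3 <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)), c(0, 1))
  tau <- 0.5
  S <- (p2 / sqrt(rowSums(p2^2))) %*% t(p3 / sqrt(rowSums(p3^2))) / tau
  ce_row <- -mean(log(exp(diag(S)) / rowSums(exp(S))))
  St <- t(S)
  ce_col <- -mean(log(exp(diag(St)) / rowSums(exp(St))))
  expect_equal(gta_infomax_loss(p2, p3, temperature = tau),
               (ce_row + ce_col) / 2, tolerance = 1e-6)
})

test_that("total_loss is the exact weighted sum and rejects negative weights", {
  comp <- list(L_node = 1, L_edge_2D = 2, L_edge_3D = 0, L_2D3D = 3)
  expect_equal(total_loss(comp, loss_weights()), 6)  # all weights 1, alpha4 0
  w <- loss_weights(eta1 = 0.5, eta2 = 2, alpha1 = 3, alpha2 = 0, alpha3 = 0)
  expect_equal(total_loss(comp, w), 3 * (0.5 * 1 + 2 * 2))
  # linearity in each weight
  base <- total_loss(comp, loss_weights(alpha2 = 1))
  up <- total_loss(comp, loss_weights(alpha2 = 1 + 1e-3))
  expect_equal((up - base) / 1e-3, comp$L_2D3D, tolerance = 1e-9)
  expect_error(loss_weights(alpha1 = -1), "non-negative")
})

test_that("the combined objective's gradient is the weighted sum of component gradients", {
  cfg <- test_cfg(D = 8L)
  mols <- small_fixtures()[1:2]
  seed <- 6L
  grad_of <- function(weights) {
    m <- moltri_model(config = cfg, seed = 9L, weights = weights)
    tape <- moltri:::ad_tape()
    P <- moltri:::ps_leaves(tape, m$ps)
    out <- moltri:::fwd_loss_bundle(tape, P, m, mols, seed = seed)
    moltri:::ad_backward(tape, out$total)
    moltri:::ps_grads(m$ps, P)
  }
  g_all <- grad_of(loss_weights(alpha1 = 1, alpha2 = 1, alpha3 = 1))
  g_c <- grad_of(loss_weights(alpha1 = 1, alpha2 = 0, alpha3 = 0))
  g_23 <- grad_of(loss_weights(alpha1 = 0, alpha2 = 1, alpha3 = 0))
  g_32 <- grad_of(loss_weights(alpha1 = 0, alpha2 = 0, alpha3 = 1))
  for (nm in c("enc2d.embed.W", "enc3d.embed.W", "score23.trunk.l1.W",
               "head.disto.W")) {
    expect_lt(max(abs(g_all[[nm]] - (g_c[[nm]] + g_23[[nm]] + g_32[[nm]]))),
              1e-8)
  }
})

test_that("edge-objective training transfers edge information across modalities", {
  run <- edge_transfer_run()
  expect_gte(run$trained$bond, 0.95)
  expect_gte(run$trained$disto, 0.90)
})
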
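# Perturbation kernels against closed forms, score-network symmetry
# properties, and the denoising score-matching losses.

test_that("kernel std is increasing and the VP mean matches quadrature", {
  ve <- sde_schedule("ve"); vp <- sde_schedule("vp")
  tt <- seq(ve$t_eps, 1, length.out = 50)
  expect_true(all(diff(ve$std(tt)) > 0))
  expect_true(all(diff(vp$std(tt)) > 0))
  # VP kernel mean coefficient equals exp(-1/2 int_0^t beta) by quadrature
  for (t in c(0.1, 0.5, 0.9)) {
    q <- stats::integrate(function(s) vp$beta_min + s * (vp$beta_max - vp$beta_min),
                          0, t)$value
    expect_lt(abs(vp$mean_coef(t) - exp(-0.5 * q)), 1e-4)
  }
  expect_error(sde_schedule("ve", sigma_min = 2, sigma_max = 1))
})

test_that("perturb_3d is deterministic, small at t_eps, with correct std", {
  m <- small_fixtures()[[1]]
  sch <- sde_schedule("ve")
  a <- perturb_3d(m$g3d, 0.4, sch, seed = 9L)
  b <- perturb_3d(m$g3d, 0.4, sch, seed = 9L)
  expect_identical(a$x_t, b$x_t)
  tiny <- perturb_3d(m$g3d, sch$t_eps, sch, seed = 2L)
  expect_lt(max(abs(tiny$x_t - tiny$clean)), 0.1)   # sigma_min ~ 0.01
  expect_error(perturb_3d(m$g3d, 0, sch), "must lie in")
  # Monte-Carlo std: many entries at a fixed t
  big <- matrix(0, 5000L, 3L)
  p <- perturb_3d(big, 0.5, sch, seed = 1L)
  expect_lt(abs(stats::sd(p$x_t) - sch$std(0.5)) / sch$std(0.5), 0.02)
  # closed-form score at the sample
  expect_equal(p$score, -(p$x_t - p$clean) / sch$std(0.5)^2, tolerance = 1e-12)
})

test_that("perturb_2d relaxes one-hots with independent node/edge streams", {
  g <- ethanol_entry()$g2d
  sch <- sde_schedule("vp")
  near <- perturb_2d(g, sch$t_eps, sch, seed = 3L)
  expect_lt(max(abs(near$V_t - near$clean_V)), 0.2)
  a <- perturb_2d(g, 0.5, sch, seed = 3L)
  b <- perturb_2d(g, 0.5, sch, seed = 3L, seed_edges = 99L)
  expect_identical(a$V_t, b$V_t)         # node stream untouched
  expect_false(identical(a$E_t, b$E_t))  # edge stream re-seeded
  cc <- perturb_2d(g, 0.5, sch, seed = 3L, seed_nodes = 99L)
  expect_identical(a$E_t, cc$E_t)
  expect_false(identical(a$V_t, cc$V_t))
})

test_that("the 2D-to-3D score network is rotation-equivariant and translation-invariant", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 4L)
  # give the zero-initialized output head nonzero weights for a real check
  model$ps$val[["score23.w.W"]][] <- rnorm(length(model$ps$val[["score23.w.W"]]), 0, 0.3)
  m <- small_fixtures()[[2]]
  h2d <- model_encode(list(m), model, "2d")$h
  x <- perturb_3d(m$g3d, 0.3, model$sched3d, seed = 1L)$x_t
  S <- score_2d_to_3d(x, h2d, 0.3, model)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  SR <- score_2d_to_3d(x %*% R, h2d, 0.3, model)
  expect_lt(max(abs(SR - S %*% R)) / max(abs(S)), 1e-4)
  St <- score_2d_to_3d(sweep(x, 2L, c(3, -2, 5), "+"), h2d, 0.3, model)
  expect_lt(max(abs(St - S)), 1e-5)
  expect_error(score_2d_to_3d(x[-1, ], h2d, 0.3, model), "mismatch")
})

test_that("a zero-initialized score head outputs exactly zero", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 4L)
  m <- small_fixtures()[[1]]
  h2d <- model_encode(list(m), model, "2d")$h
  S <- score_2d_to_3d(m$g3d$coords, h2d, 0.5, model)
  expect_equal(S, matrix(0, m$g3d$n, 3L))
  st3 <- model_encode(list(m), model, "3d")
  ns <- perturb_2d(m$g2d, 0.5, model$sched2d, seed = 1L)
  z3 <- match_pair_rows(st3, ns$pairs)
  out <- score_3d_to_2d(ns, st3$h, z3, 0.5, model)
  expect_true(all(out$V == 0))
  expect_true(all(out$E == 0))
})

test_that("the 3D-to-2D score network inherits rigid-motion invariance", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 6L)
  model$ps$val[["score32.vout.W"]][] <- rnorm(length(model$ps$val[["score32.vout.W"]]), 0, 0.3)
  model$ps$val[["score32.eout.W"]][] <- rnorm(length(model$ps$val[["score32.eout.W"]]), 0, 0.3)
  m <- small_fixtures()[[3]]
  ns <- perturb_2d(m$g2d, 0.4, model$sched2d, seed = 2L)
  st <- model_encode(list(m), model, "3d")
  out <- score_3d_to_2d(ns, st$h, match_pair_rows(st, ns$pairs), 0.4, model)
  g3r <- build_graph3d(moltri:::rigid_motion(m$g3d$coords), m$g3d$z)
  str <- model_encode(list(list(g2d = m$g2d, g3d = g3r)), model, "3d")
  outr <- score_3d_to_2d(ns, str$h, match_pair_rows(str, ns$pairs), 0.4, model)
  expect_lt(max(abs(outr$V - out$V)) / max(abs(out$V)), 1e-4)
  # consistent atom permutation permutes the node-score rows
  pi <- sample.int(m$g2d$n)
  g2p <- moltri:::permute_graph2d(m$g2d, pi)
  g3p <- moltri:::permute_graph3d(m$g3d, pi)
  # build the permuted noised sample directly: row i of V_t moves to pi[i]
  nsp <- ns
  nsp$V_t <- matrix(0, nrow(ns$V_t), ncol(ns$V_t))
  nsp$V_t[pi, ] <- ns$V_t
  nsp$E_t <- ns$E_t
  nsp$pairs <- data.frame(u = pi[ns$pairs$u], v = pi[ns$pairs$v])
  stp <- model_encode(list(list(g2d = g2p, g3d = g3p)), model, "3d")
  outp <- score_3d_to_2d(nsp, stp$h, match_pair_rows(stp, nsp$pairs), 0.4, model)
  expect_lt(max(abs(outp$V[pi, , drop = FALSE] - out$V)), 1e-5)
})

test_that("the kernel-score oracle drives both score-matching losses to zero", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  mols <- small_fixtures()[1:3]
  l23 <- loss_2d_to_3d(mols, model, seed = 5L,
                       score_override = function(ns, i) ns$score)
  expect_equal(l23, 0)
  l32 <- loss_3d_to_2d(mols, model, seed = 5L,
                       score_override = function(ns, i) {
                         list(V = ns$score_V, E = ns$score_E)
                       })
  expect_equal(l32, 0)
  # and both are non-negative with the real (zero-initialized) network
  expect_gte(loss_2d_to_3d(mols, model, seed = 5L), 0)
  expect_gte(loss_3d_to_2d(mols, model, seed = 5L), 0)
})

test_that("zero-network weighted loss matches the Gaussian identity", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  m <- small_fixtures()[[1]]
  n <- m$g3d$n
  zero23 <- function(ns, i) ns$score * 0
  draws <- vapply(1:2000, function(k) {
    loss_2d_to_3d(list(m), model, seed = k, score_override = zero23)
  }, 0)
  expect_lt(abs(mean(draws) - 3 * n) / (3 * n), 0.05)
  zero32 <- function(ns, i) list(V = ns$score_V * 0, E = ns$score_E * 0)
  ft <- moltri:::relax_2d_features(m$g2d)
  dim_total <- length(ft$V) + length(ft$E)
  draws32 <- vapply(1:2000, function(k) {
    loss_3d_to_2d(list(m), model, seed = k, score_override = zero32)
  }, 0)
  expect_lt(abs(mean(draws32) - dim_total) / dim_total, 0.05)
})

test_that("loss distribution is invariant to rigid motion of the clean conformation", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 3L)
  set.seed(77)
  model$ps$val[["score23.w.W"]][] <- rnorm(length(model$ps$val[["score23.w.W"]]), 0, 0.2)
  m <- small_fixtures()[[2]]
  mr <- list(g2d = m$g2d,
             g3d = build_graph3d(moltri:::rigid_motion(m$g3d$coords), m$g3d$z))
  la <- vapply(1:40, function(k) loss_2d_to_3d(list(m), model, seed = k), 0)
  lb <- vapply(1:40, function(k) loss_2d_to_3d(list(mr), model, seed = k), 0)
  expect_lt(abs(mean(la) - mean(lb)) / mean(la), 0.1)
})

test_that("fixed seeds reproduce both losses exactly", {
  cfg <- test_cfg(D = 8L)
  model <- moltri_model(config = cfg, seed = 2L)
  mols <- small_fixtures()[1:2]
  expect_identical(loss_2d_to_3d(mols, model, seed = 11L),
                   loss_2d_to_3d(mols, model, seed = 11L))
  expect_identical(loss_3d_to_2d(mols, model, seed = 11L),
                   loss_3d_to_2d(mols, model, seed = 11L))
})
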
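# Forward SDEs, perturbation kernels, score networks, and denoising
# score-matching losses for the two cross-modal generation directions.
#
# 3D coordinates follow a variance-exploding (VE) SDE; relaxed (continuous
# one-hot) 2D node and edge features follow a variance-preserving (VP) SDE
# with independent Brownian motions for the node and edge streams. Both
# kernels are Gaussian with closed-form mean coefficient m(t) and std s(t), so
# the true score -(x_t - m x_0)/s^2 is available during training.

#' Forward SDE schedule
#'
#' @param kind `"ve"` (variance-exploding; default for 3D coordinates) or
#'   `"vp"` (variance-preserving; default for relaxed 2D features).
#' @param sigma_min,sigma_max VE noise scale range (Angstrom).
#' @param beta_min,beta_max VP noise rate range.
#' @param t_eps smallest sampled diffusion time (times are in `[t_eps, 1]`).
#' @return an `sde_schedule` with closed-form `mean_coef(t)`, `std(t)`,
#'   `drift(x, t)` and `diffusion(t)` functions. The kernel std is strictly
#'   increasing in t for both kinds.
#' @export
sde_schedule <- function(kind = c("ve", "vp"),
                         sigma_min = 0.01, sigma_max = 2.0,
                         beta_min = 0.1, beta_max = 9.5,
                         t_eps = 1e-3) {
  kind <- match.arg(kind)
  stopifnot(t_eps > 0, t_eps < 1)
  if (kind == "ve") {
    stopifnot(sigma_min > 0, sigma_min < sigma_max)
    ratio <- sigma_max / sigma_min
    sch <- list(kind = kind, sigma_min = sigma_min, sigma_max = sigma_max,
                t_eps = t_eps,
                mean_coef = function(t) rep(1, length(t)),
                std = function(t) sigma_min * ratio^t,
                drift = function(x, t) x * 0,
                diffusion = function(t) sigma_min * ratio^t * sqrt(2 * log(ratio)))
  } else {
    stopifnot(beta_min > 0, beta_min < beta_max)
    beta <- function(t) beta_min + t * (beta_max - beta_min)
    mc <- function(t) exp(-0.25 * t^2 * (beta_max - beta_min) - 0.5 * t * beta_min)
    sch <- list(kind = kind, beta_min = beta_min, beta_max = beta_max,
                t_eps = t_eps,
                mean_coef = mc,
                std = function(t) sqrt(pmax(1 - mc(t)^2, 1e-12)),
                drift = function(x, t) -0.5 * beta(t) * x,
                diffusion = function(t) sqrt(beta(t)))
  }
  class(sch) <- "sde_schedule"
  sch
}

check_time <- function(t, schedule) {
  if (any(t < schedule$t_eps | t > 1)) {
    stop("diffusion time t must lie in [", schedule$t_eps, ", 1]")
  }
  invisible(t)
}

#' Perturb a 3D conformation under the forward SDE
#'
#' Coordinates are centered (zero mean) before perturbation so the
#' translation-invariant score is well defined, then diffused under the
#' Gaussian perturbation kernel: `x_t = m(t) x_0 + s(t) eps`. The closed-form
#' kernel score `-(x_t - m(t) x_0) / s(t)^2` is returned alongside.
#'
#' @param g3d a `Graph3D` (or bare n x 3 coordinate matrix).
#' @param t diffusion time in `[t_eps, 1]`.
#' @param schedule an [sde_schedule()]; VE by default.
#' @param seed integer seed; sampling is deterministic per seed.
#' @return a `noised_sample` list with `x_t`, `clean` (centered x_0), `t`,
#'   `eps`, and `score`.
#' @export
perturb_3d <- function(g3d, t, schedule = sde_schedule("ve"), seed = 1L) {
  coords <- if (inherits(g3d, "Graph3D")) g3d$coords else as.matrix(g3d)
  check_time(t, schedule)
  x0 <- sweep(coords, 2L, colMeans(coords))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "perturb_3d"))
  eps <- matrix(stats::rnorm(length(x0)), nrow(x0))
  m <- schedule$mean_coef(t); s <- schedule$std(t)
  x_t <- m * x0 + s * eps
  structure(list(x_t = x_t, clean = x0, t = t, eps = eps,
                 score = -(x_t - m * x0) / s^2, std = s, mean_coef = m),
            class = "noised_sample")
}

# Relaxed continuous feature matrices of a 2D graph: node features and
# directed-bond one-hots.
relax_2d_features <- function(g2d) {
  list(V = featurize_nodes_2d(g2d),
       E = featurize_bonds(g2d$bond_type),
       pairs = data.frame(u = g2d$bond_u, v = g2d$bond_v))
}

#' Perturb relaxed 2D graph features under the forward SDE
#'
#' Node and edge one-hot features are relaxed to continuous vectors and
#' diffused under the VP kernel with independent noise streams for the node
#' and edge components (different seeds change only their own component).
#'
#' @param g2d a `Graph2D`.
#' @inheritParams perturb_3d
#' @return a `noised_sample` list with components `V_t`, `E_t`, clean
#'   features, per-component scores, and `t`.
#' @export
perturb_2d <- function(g2d, t, schedule = sde_schedule("vp"), seed = 1L,
                       seed_nodes = NULL, seed_edges = NULL) {
  check_time(t, schedule)
  ft <- relax_2d_features(g2d)
  m <- schedule$mean_coef(t); s <- schedule$std(t)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed_nodes %||% seed, "perturb_2d_nodes"))
  eps_v <- matrix(stats::rnorm(length(ft$V)), nrow(ft$V))
  set.seed(derive_seed(seed_edges %||% seed, "perturb_2d_edges"))
  eps_e <- if (length(ft$E)) matrix(stats::rnorm(length(ft$E)), nrow(ft$E)) else ft$E
  V_t <- m * ft$V + s * eps_v
  E_t <- if (length(ft$E)) m * ft$E + s * eps_e else ft$E
  structure(list(V_t = V_t, E_t = E_t, clean_V = ft$V, clean_E = ft$E,
                 pairs = ft$pairs, t = t, eps_V = eps_v, eps_E = eps_e,
                 score_V = -(V_t - m * ft$V) / s^2,
                 score_E = if (length(ft$E)) -(E_t - m * ft$E) / s^2 else ft$E,
                 std = s, mean_coef = m),
            class = "noised_sample")
}

## ---- score networks ----------------------------------------------------------

SCORE_HIDDEN <- 64L
N_TIME_FREQ <- 4L

# Fixed sinusoidal time features plus the schedule's m(t) and s(t).
time_embedding <- function(t, schedule) {
  freqs <- 2^(0:(N_TIME_FREQ - 1L))
  emb <- c(sin(pi * freqs * t), cos(pi * freqs * t),
           schedule$mean_coef(t), schedule$std(t))
  matrix(emb, 1L)
}

TIME_DIM <- 2L * N_TIME_FREQ + 2L

init_score23_params <- function(ps, prefix, cfg, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("init.", prefix)))
  d_in <- 2L * cfg$D_h + cfg$n_rbf + TIME_DIM
  ps_add_mlp(ps, paste0(prefix, ".trunk"), c(d_in, SCORE_HIDDEN, SCORE_HIDDEN))
  ps_add_linear(ps, paste0(prefix, ".w"), SCORE_HIDDEN, 1L, zero = TRUE)
  ps_add_linear(ps, paste0(prefix, ".disc"), SCORE_HIDDEN, 1L)
  invisible(ps)
}

init_score32_params <- function(ps, prefix, cfg, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("init.", prefix)))
  dv <- N_NODE_FEAT + cfg$D_h + TIME_DIM
  de <- N_BOND_FEAT + cfg$D_z + TIME_DIM
  ps_add_mlp(ps, paste0(prefix, ".vtrunk"), c(dv, SCORE_HIDDEN, SCORE_HIDDEN))
  ps_add_linear(ps, paste0(prefix, ".vout"), SCORE_HIDDEN, N_NODE_FEAT, zero = TRUE)
  ps_add_mlp(ps, paste0(prefix, ".etrunk"), c(de, SCORE_HIDDEN, SCORE_HIDDEN))
  ps_add_linear(ps, paste0(prefix, ".eout"), SCORE_HIDDEN, N_BOND_FEAT, zero = TRUE)
  ps_add_linear(ps, paste0(prefix, ".disc"), SCORE_HIDDEN, 1L)
  invisible(ps)
}

# SE(3)-equivariant score: S_u = sum_v w_uv (x_u - x_v), with scalar pair
# weights from an MLP over condition embeddings, the radial expansion of the
# *noised* pair distance, and the time embedding. Rotations act on (x_u - x_v)
# only, so S rotates with the input; translations cancel.
fwd_score23 <- function(tape, P, prefix, xt, cond_h, batch3, t_mol, schedule, cfg) {
  pairs <- batch3$pairs
  n <- batch3$n
  temb <- do.call(rbind, lapply(t_mol, time_embedding, schedule = schedule))
  temb_pair <- temb[pairs$mol, , drop = FALSE]
  d <- fwd_pair_dist(tape, xt, pairs)
  rb <- fwd_rbf(tape, d, cfg)
  hu <- ad_gather_rows(tape, cond_h, pairs$u)
  hv <- ad_gather_rows(tape, cond_h, pairs$v)
  inp <- ad_concat_cols(tape, list(hu, hv, rb, temb_pair))
  hid <- ad_relu(tape, nn_mlp(tape, P, paste0(prefix, ".trunk"), inp, 2L))
  w <- nn_linear(tape, P, paste0(prefix, ".w"), hid)
  xu <- ad_gather_rows(tape, xt, pairs$u)
  xv <- ad_gather_rows(tape, xt, pairs$v)
  rel <- ad_sub(tape, xu, xv)
  contrib <- ad_mul(tape, rel, ad_index_cols(tape, w, c(1L, 1L, 1L)))
  S <- ad_scatter_sum(tape, contrib, pairs$u, n)
  pool <- ad_scatter_sum(tape, hid, pairs$mol, batch3$n_mol)
  pool <- ad_mul(tape, pool,
                 matrix(1 / pmax(tabulate(pairs$mol, batch3$n_mol), 1L),
                        batch3$n_mol, SCORE_HIDDEN))
  disc <- nn_linear(tape, P, paste0(prefix, ".disc"), pool)
  list(score = S, disc = disc)
}

# SE(3)-invariant score over relaxed 2D features: per-node and per-edge MLPs
# conditioned on the (rigid-motion invariant) 3D embeddings.
fwd_score32 <- function(tape, P, prefix, Vt, Et, cond_h, cond_z, mol_id,
                        pair_mol, t_mol, schedule, n_mol) {
  temb <- do.call(rbind, lapply(t_mol, time_embedding, schedule = schedule))
  vin <- ad_concat_cols(tape, list(Vt, cond_h, temb[mol_id, , drop = FALSE]))
  vhid <- ad_relu(tape, nn_mlp(tape, P, paste0(prefix, ".vtrunk"), vin, 2L))
  vscore <- nn_linear(tape, P, paste0(prefix, ".vout"), vhid)
  escore <- NULL
  if (!is.null(Et) && nrow(ad_val(Et)) > 0L) {
    ein <- ad_concat_cols(tape, list(Et, cond_z, temb[pair_mol, , drop = FALSE]))
    ehid <- ad_relu(tape, nn_mlp(tape, P, paste0(prefix, ".etrunk"), ein, 2L))
    escore <- nn_linear(tape, P, paste0(prefix, ".eout"), ehid)
  }
  pool <- ad_scatter_sum(tape, vhid, mol_id, n_mol)
  pool <- ad_mul(tape, pool,
                 matrix(1 / pmax(tabulate(mol_id, n_mol), 1L), n_mol, SCORE_HIDDEN))
  disc <- nn_linear(tape, P, paste0(prefix, ".disc"), pool)
  list(V = vscore, E = escore, disc = disc)
}

#' Evaluate the SE(3)-equivariant 2D-to-3D score network
#'
#' @param coords noised coordinates (n x 3).
#' @param h2d conditioning node embeddings from [gta2d_encode()] of the paired
#'   2D graph (n x D_h matrix).
#' @param t diffusion time.
#' @param model a [moltri_model()].
#' @return n x 3 score matrix. Rotating `coords` rotates the output; global
#'   translation leaves it unchanged.
#' @export
score_2d_to_3d <- function(coords, h2d, t, model) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(h2d)) {
    stop("atom count mismatch: coords have ", nrow(coords),
         " rows, condition has ", nrow(h2d))
  }
  check_time(t, model$sched3d)
  batch <- build_batch3d(list(build_graph3d(coords, rep(6L, nrow(coords)))),
                         model$config)
  out <- fwd_score23(NULL, model$ps$val, "score23", coords, h2d, batch,
                     t, model$sched3d, model$config)
  ad_val(out$score)
}

#' Evaluate the SE(3)-invariant 3D-to-2D score network
#'
#' @param noised a `noised_sample` from [perturb_2d()] (fields `V_t`, `E_t`,
#'   `pairs`).
#' @param h3d,z3d conditioning node and pair embeddings from [gta3d_encode()]
#'   of the paired conformation; `z3d` rows must follow the bonded ordered
#'   pair order of `noised$pairs` (use [match_pair_rows()]).
#' @inheritParams score_2d_to_3d
#' @return list with `V` (node-feature score) and `E` (edge-feature score).
#' @export
score_3d_to_2d <- function(noised, h3d, z3d, t, model) {
  if (nrow(noised$V_t) != nrow(h3d)) {
    stop("atom count mismatch: noised sample has ", nrow(noised$V_t),
         " atoms, condition has ", nrow(h3d))
  }
  check_time(t, model$sched2d)
  n <- nrow(h3d)
  out <- fwd_score32(NULL, model$ps$val, "score32", noised$V_t, noised$E_t,
                     h3d, z3d, rep(1L, n), rep(1L, nrow(noised$E_t)),
                     t, model$sched2d, 1L)
  list(V = ad_val(out$V), E = if (is.null(out$E)) NULL else ad_val(out$E))
}

#' Look up 3D pair-embedding rows for a set of ordered pairs
#'
#' @param state an `EmbeddingState` from [gta3d_encode()].
#' @param pairs data.frame with `u`, `v` (node indices into the state).
#' @return matrix of `z` rows aligned with `pairs`.
#' @export
match_pair_rows <- function(state, pairs) {
  key_state <- paste(state$pairs$u, state$pairs$v)
  idx <- match(paste(pairs$u, pairs$v), key_state)
  if (anyNA(idx)) stop("requested pair not present in embedding state")
  state$z[idx, , drop = FALSE]
}

## ---- denoising score-matching losses ---------------------------------------

sample_times <- function(n, schedule, seed, stream) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, stream))
  stats::runif(n, schedule$t_eps, 1)
}

# Internal tape version; score_override (function(sample, mol_index) -> score
# matrices) replaces the network, for kernel-score oracle checks.
fwd_loss_2d_to_3d <- function(tape, P, model, mols, seed, t_mol = NULL,
                              weighting = "std2", score_override = NULL,
                              cond_h = NULL, batch3 = NULL) {
  sch <- model$sched3d
  n_mol <- length(mols)
  if (is.null(t_mol)) t_mol <- sample_times(n_mol, sch, seed, "t23")
  g3ds <- lapply(mols, `[[`, "g3d")
  if (is.null(batch3)) batch3 <- build_batch3d(g3ds, model$config)
  if (is.null(cond_h) && is.null(score_override)) {
    batch2 <- build_batch2d(lapply(mols, `[[`, "g2d"), model$config)
    cond_h <- fwd_encode(tape, P, "enc2d", batch2, model$config, "2d")$h
  }
  noised <- lapply(seq_len(n_mol), function(i) {
    perturb_3d(g3ds[[i]], t_mol[i], sch, seed = derive_seed(seed, paste0("n23.", i)))
  })
  xt <- do.call(rbind, lapply(noised, `[[`, "x_t"))
  true_score <- do.call(rbind, lapply(noised, `[[`, "score"))
  if (is.null(score_override)) {
    S <- fwd_score23(tape, P, "score23", xt, cond_h, batch3, t_mol, sch,
                     model$config)$score
  } else {
    S <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
      score_override(noised[[i]], i)
    }))
  }
  resid <- ad_square(tape, ad_sub(tape, S, true_score))
  w_node <- if (weighting == "std2") sch$std(t_mol)[batch3$mol_id]^2 else
    rep(1, batch3$n)
  weighted <- ad_mul(tape, resid, matrix(w_node, batch3$n, 3L))
  ad_affine(tape, ad_sum(tape, weighted), mult = 1 / n_mol)
}

fwd_loss_3d_to_2d <- function(tape, P, model, mols, seed, t_mol = NULL,
                              weighting = "std2", score_override = NULL,
                              cond = NULL) {
  sch <- model$sched2d
  n_mol <- length(mols)
  if (is.null(t_mol)) t_mol <- sample_times(n_mol, sch, seed, "t32")
  g2ds <- lapply(mols, `[[`, "g2d")
  if (is.null(cond) && is.null(score_override)) {
    batch3 <- build_batch3d(lapply(mols, `[[`, "g3d"), model$config)
    enc <- fwd_encode(tape, P, "enc3d", batch3, model$config, "3d")
    # bonded ordered pairs of each molecule, looked up in the fully connected set
    b2 <- build_batch2d(g2ds, model$config)
    zidx <- batch3$pid[cbind(b2$pairs$u, b2$pairs$v)]
    cond <- list(h = enc$h,
                 z = if (b2$pairs$n) ad_gather_rows(tape, enc$z, zidx) else NULL,
                 mol_id = batch3$mol_id, pair_mol = b2$pairs$mol)
  }
  noised <- lapply(seq_len(n_mol), function(i) {
    perturb_2d(g2ds[[i]], t_mol[i], sch, seed = derive_seed(seed, paste0("n32.", i)))
  })
  Vt <- do.call(rbind, lapply(noised, `[[`, "V_t"))
  Et <- do.call(rbind, lapply(noised, `[[`, "E_t"))
  sV <- do.call(rbind, lapply(noised, `[[`, "score_V"))
  sE <- do.call(rbind, lapply(noised, `[[`, "score_E"))
  n_nodes <- nrow(Vt)
  node_mol <- rep(seq_len(n_mol), vapply(g2ds, function(g) g$n, 1L))
  bond_mol <- rep(seq_len(n_mol), vapply(g2ds, function(g) length(g$bond_u), 1L))
  if (is.null(score_override)) {
    out <- fwd_score32(tape, P, "score32", Vt, if (nrow(Et)) Et else NULL,
                       cond$h, cond$z, cond$mol_id, cond$pair_mol,
                       t_mol, sch, n_mol)
  } else {
    ov <- lapply(seq_len(n_mol), function(i) score_override(noised[[i]], i))
    out <- list(V = do.call(rbind, lapply(ov, `[[`, "V")),
                E = do.call(rbind, lapply(ov, `[[`, "E")))
  }
  wV <- if (weighting == "std2") sch$std(t_mol)[node_mol]^2 else rep(1, n_nodes)
  lv <- ad_sum(tape, ad_mul(tape, ad_square(tape, ad_sub(tape, out$V, sV)),
                            matrix(wV, n_nodes, ncol(Vt))))
  total <- lv
  if (nrow(Et) && !is.null(out$E)) {
    wE <- if (weighting == "std2") sch$std(t_mol)[bond_mol]^2 else
      rep(1, nrow(Et))
    le <- ad_sum(tape, ad_mul(tape, ad_square(tape, ad_sub(tape, out$E, sE)),
                              matrix(wE, nrow(Et), ncol(Et))))
    total <- ad_add(tape, lv, le)
  }
  ad_affine(tape, total, mult = 1 / n_mol)
}

#' Denoising score-matching loss for 2D-to-3D generation
#'
#' Monte-Carlo estimate: one uniform time per molecule, perturb the (centered)
#' conformation under the VE kernel, and penalize the squared deviation of the
#' network score from the closed-form kernel score, weighted by `std(t)^2`
#' (so a zero network has expectation 3 x atom count). The unweighted printed
#' form is available via `weighting = "none"`.
#'
#' @param mols list of paired entries (`g2d` + `g3d`).
#' @param model a [moltri_model()].
#' @param seed integer seed for times and noise.
#' @param weighting `"std2"` (default) or `"none"`.
#' @param t optional fixed time(s) overriding the uniform draw.
#' @param score_override optional `function(noised_sample, i)` used in place of
#'   the network (e.g. the kernel-score oracle, which drives the loss to 0).
#' @return scalar loss (>= 0).
#' @export
loss_2d_to_3d <- function(mols, model, seed = 1L,
                          weighting = c("std2", "none"), t = NULL,
                          score_override = NULL) {
  weighting <- match.arg(weighting)
  weighting <- if (weighting == "std2") "std2" else "none"
  if (!is.null(t)) t <- rep_len(t, length(mols))
  as.numeric(ad_val(fwd_loss_2d_to_3d(NULL, model$ps$val, model, mols, seed,
                                      t_mol = t, weighting = weighting,
                                      score_override = score_override)))
}

#' Denoising score-matching loss for 3D-to-2D reconstruction
#'
#' Mirror of [loss_2d_to_3d()] over the relaxed 2D node and edge features
#' under the VP kernel; a zero network has expectation equal to the total
#' relaxed feature dimension.
#'
#' @inheritParams loss_2d_to_3d
#' @export
loss_3d_to_2d <- function(mols, model, seed = 1L,
                          weighting = c("std2", "none"), t = NULL,
                          score_override = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(t)) t <- rep_len(t, length(mols))
  as.numeric(ad_val(fwd_loss_3d_to_2d(NULL, model$ps$val, model, mols, seed,
                                      t_mol = t, weighting = weighting,
                                      score_override = score_override)))
}
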
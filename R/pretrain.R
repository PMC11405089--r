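# Pretraining orchestration: batching, optimization, logging, checkpoints,
# and checkpoint diagnostics.

#' Pretrain the full model on paired molecules
#'
#' Every step draws a batch, computes all enabled loss components (node
#' contrastive, both edge objectives, both score-matching objectives, optional
#' InfoNCE), applies one Adam update, and logs the loss bundle. A NaN in any
#' component aborts with the offending component named. Runs are deterministic
#' for a fixed seed (single-threaded).
#'
#' @param mols list of paired entries (>= 2; the contrastive term needs
#'   negatives).
#' @param model a [moltri_model()]; created from `config`/`seed` when NULL.
#' @param steps number of optimizer steps.
#' @param batch_size molecules per step (capped at `length(mols)`).
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip.
#' @param seed integer seed driving batching, diffusion times and noise.
#' @param config,weights used when `model` is NULL.
#' @param log_path optional JSONL path; one line per step with every enabled
#'   loss component.
#' @param checkpoint_path,checkpoint_every optional checkpointing (RDS).
#' @param start_step resume counter (used when continuing from a checkpoint).
#' @return the trained model; `attr(, "history")` is a data.frame of loss
#'   components per step.
#' @export
pretrain <- function(mols, model = NULL, steps = 100L, batch_size = 8L,
                     lr = 1e-4, clip = 10, seed = 1L,
                     config = encoder_config(), weights = loss_weights(),
                     log_path = NULL, checkpoint_path = NULL,
                     checkpoint_every = 0L, start_step = 0L) {
  if (length(mols) < 2L) stop("pretraining needs at least 2 paired molecules")
  if (is.null(model)) {
    model <- moltri_model(config = config, seed = seed, weights = weights)
  }
  n <- length(mols)
  bs <- min(batch_size, n)
  history <- vector("list", steps)
  if (!is.null(log_path) && start_step == 0L && file.exists(log_path)) {
    unlink(log_path)
  }
  for (s in seq_len(steps)) {
    step <- start_step + s
    idx <- if (bs == n) seq_len(n) else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, paste0("batch.", step)))
      i <- sample.int(n, bs)
      .Random.seed_restore(old)
      i
    }
    tape <- ad_tape()
    P <- ps_leaves(tape, model$ps)
    out <- fwd_loss_bundle(tape, P, model, mols[idx],
                           seed = derive_seed(seed, paste0("step.", step)))
    bad <- names(out$components)[!vapply(out$components, is.finite, TRUE)]
    if (length(bad)) {
      stop("non-finite loss component ", bad[1], " at step ", step)
    }
    ad_backward(tape, out$total)
    adam_step(model$ps, ps_grads(model$ps, P), lr = lr, clip = clip)
    rec <- c(list(step = step), out$components)
    history[[s]] <- rec
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = log_path, append = TRUE, sep = "")
    }
    if (!is.null(checkpoint_path) && checkpoint_every > 0L &&
        step %% checkpoint_every == 0L) {
      save_checkpoint(model, checkpoint_path, step = step)
    }
  }
  attr(model, "history") <- do.call(rbind, lapply(history, function(r) {
    as.data.frame(r)
  }))
  model
}

#' Train only the cross-modal edge objectives
#'
#' Optimizes `L_edge_2D + L_edge_3D` (or one of them), the desk-scale route to
#' demonstrating cross-modal edge-information transfer: bond types become
#' decodable from 3D pair embeddings and distance bins from 2D edge
#' embeddings.
#'
#' @inheritParams pretrain
#' @param which `"both"`, `"2d"` or `"3d"`.
#' @export
train_edge_objectives <- function(mols, model = NULL, steps = 300L,
                                  batch_size = length(mols), lr = 3e-3,
                                  seed = 1L, config = encoder_config(),
                                  which = c("both", "2d", "3d")) {
  which <- match.arg(which)
  if (is.null(model)) model <- moltri_model(config = config, seed = seed)
  n <- length(mols)
  bs <- min(batch_size, n)
  for (s in seq_len(steps)) {
    idx <- if (bs == n) seq_len(n) else {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, paste0("ebatch.", s)))
      i <- sample.int(n, bs)
      .Random.seed_restore(old)
      i
    }
    tape <- ad_tape()
    P <- ps_leaves(tape, model$ps)
    total <- NULL
    if (which %in% c("both", "2d")) {
      total <- fwd_edge_loss_2d(tape, P, model, mols[idx])
    }
    if (which %in% c("both", "3d")) {
      l3 <- fwd_edge_loss_3d(tape, P, model, mols[idx])
      total <- if (is.null(total)) l3 else ad_add(tape, total, l3)
    }
    if (!is.finite(ad_val(total))) stop("non-finite edge loss at step ", s)
    ad_backward(tape, total)
    adam_step(model$ps, ps_grads(model$ps, P), lr = lr)
  }
  model
}

#' Edge-probe accuracies: decode labels from the pair embeddings
#'
#' @param mols held-out paired molecules.
#' @param model a [moltri_model()].
#' @return list with `bond` (5-class bond-type accuracy from the 3D bond head)
#'   and `disto` (distogram top-1 accuracy from the 2D distogram head), both
#'   over all unordered heavy-atom pairs.
#' @export
edge_probe_accuracy <- function(mols, model) {
  P <- model$ps$val
  cfg <- model$config
  # bond-type from z^3D
  b3 <- build_batch3d(lapply(mols, `[[`, "g3d"), cfg)
  st3 <- fwd_encode(NULL, P, "enc3d", b3, cfg, "3d")
  sel <- which(b3$pairs$u < b3$pairs$v)
  ns <- vapply(mols, function(m) m$g2d$n, 1L)
  off <- cumsum(c(0L, utils::head(ns, -1L)))
  labs <- integer(length(sel))
  for (i in seq_along(mols)) {
    lab <- bond_labels(mols[[i]]$g2d)
    loc <- which(b3$pairs$mol[sel] == i)
    labs[loc] <- lab[cbind(b3$pairs$u[sel][loc] - off[i],
                           b3$pairs$v[sel][loc] - off[i])]
  }
  logits_b <- ad_val(nn_linear(NULL, P, "head.bond",
                               ad_val(st3$z)[sel, , drop = FALSE]))
  bond_acc <- mean(max.col(logits_b, ties.method = "first") == labs)
  # distance bin from z^2D
  b2 <- build_batch2d(lapply(mols, `[[`, "g2d"), cfg)
  st2 <- fwd_encode(NULL, P, "enc2d", b2, cfg, "2d")
  tab <- disto_pair_table(mols, b2, bonded_only = FALSE)
  true_bin <- bin_distance(tab$d, model$binspec) + 1L
  h <- ad_val(st2$h)
  zx <- rbind(ad_val(st2$z), P[["head.disto.null"]])
  zid <- ifelse(tab$zid == 0L, b2$pairs$n + 1L, tab$zid)
  inp <- cbind(h[tab$u, , drop = FALSE] + h[tab$v, , drop = FALSE],
               zx[zid, , drop = FALSE])
  logits_d <- ad_val(nn_linear(NULL, P, "head.disto", inp))
  disto_acc <- mean(max.col(logits_d, ties.method = "first") == true_bin)
  list(bond = bond_acc, disto = disto_acc)
}

#' Diagnostics report for a checkpoint
#'
#' Runs the invariance suite (SE(3) on the 3D encoder, permutation
#' equivariance on both encoders), the edge-probe accuracies, and the
#' per-component losses on a held-out fixture set.
#'
#' @param model a `moltri_model` or a checkpoint path.
#' @param mols held-out paired molecules.
#' @param n_motions rigid motions per molecule in the SE(3) check.
#' @param seed integer seed.
#' @return list with `se3_max_rel_dev`, `perm_max_dev`, `attn_rowsum_dev`,
#'   `probe` accuracies and the `losses` bundle.
#' @export
evaluate_checkpoint <- function(model, mols, n_motions = 5L, seed = 1L) {
  if (is.character(model)) model <- load_checkpoint(model)
  inv <- invariance_suite(mols, model, n_motions = n_motions, seed = seed)
  probe <- edge_probe_accuracy(mols, model)
  losses <- loss_bundle(mols, model, seed = seed)
  c(inv, list(probe = probe, losses = losses))
}

#' SE(3) and permutation invariance checks for the encoders
#'
#' @inheritParams evaluate_checkpoint
#' @export
invariance_suite <- function(mols, model, n_motions = 5L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "invariance"))
  se3 <- 0; perm <- 0; attn <- 0
  for (m in mols) {
    st <- model_encode(list(m), model, "3d")
    attn <- max(attn, st$attn_rowsum_dev)
    ref <- c(st$h, st$pooled)
    scale <- max(abs(ref))
    for (k in seq_len(n_motions)) {
      g3 <- build_graph3d(rigid_motion(m$g3d$coords), m$g3d$z)
      st2 <- model_encode(list(list(g2d = m$g2d, g3d = g3)), model, "3d")
      se3 <- max(se3, max(abs(c(st2$h, st2$pooled) - ref)) / scale)
    }
    # permutation equivariance of the 2D encoder
    pi <- sample.int(m$g2d$n)
    g2p <- permute_graph2d(m$g2d, pi)
    a <- model_encode(list(m$g2d), model, "2d")
    b <- model_encode(list(g2p), model, "2d")
    perm <- max(perm, max(abs(b$h[pi, , drop = FALSE] - a$h)),
                abs(b$pooled - a$pooled))
  }
  list(se3_max_rel_dev = se3, perm_max_dev = perm, attn_rowsum_dev = attn)
}

# Relabel atoms of a 2D graph: new index of old atom i is pi[i].
permute_graph2d <- function(g2d, pi) {
  inv <- integer(length(pi))
  inv[pi] <- seq_along(pi)
  bonds <- bond_table(g2d)
  graph2d(g2d$elements[inv],
          data.frame(u = pi[bonds$u], v = pi[bonds$v], type = bonds$type),
          charges = g2d$charges[inv])
}

permute_graph3d <- function(g3d, pi) {
  inv <- integer(length(pi))
  inv[pi] <- seq_along(pi)
  build_graph3d(g3d$coords[inv, , drop = FALSE], g3d$z[inv])
}
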
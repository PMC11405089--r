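# Downstream evaluation: finetuning heads on the pooled embedding, molecular
# retrieval by cosine similarity, and circular-fingerprint similarity.

#' Rank-based ROC-AUC
#'
#' Mann-Whitney formulation (ties get half credit), identical to the fraction
#' of concordant positive/negative score pairs.
#'
#' @param scores numeric predictions.
#' @param labels binary labels (0/1); NAs are dropped.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- !is.na(labels) & !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("ROC-AUC undefined: split contains a single class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC averaged over the columns of a multi-task label matrix (NA masked).
multitask_auc <- function(scores, labels) {
  if (is.null(dim(labels))) return(roc_auc(scores, labels))
  mean(vapply(seq_len(ncol(labels)), function(j) {
    roc_auc(scores[, j], labels[, j])
  }, 0))
}

#' Pooled embeddings for a list of molecules
#'
#' @param mols list of entries (paired, or single-modality graphs).
#' @param model a [moltri_model()].
#' @param modality `"2d"` or `"3d"`.
#' @return molecules x pool_dim matrix.
#' @export
predict_pooled <- function(mols, model, modality = c("2d", "3d")) {
  model_encode(mols, model, match.arg(modality))$pooled
}

## ---- finetuning --------------------------------------------------------------

init_head_params <- function(task, pool_dim, hidden, seed) {
  ps <- ps_new()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "head"))
  if (task == "classification") {
    ps_add_linear(ps, "head.out", pool_dim, 1L)
  } else {
    ps_add_mlp(ps, "head.out2", c(pool_dim, hidden, 1L))
  }
  ps
}

fwd_head <- function(tape, P, task, pooled) {
  if (task == "classification") nn_linear(tape, P, "head.out", pooled)
  else nn_mlp(tape, P, "head.out2", pooled, 2L)
}

# Forward to pooled embeddings for a molecule batch on a tape, optionally with
# tracked coordinates (forces task differentiates through the 3D pathway).
fwd_pooled <- function(tape, P, model, mols, modality, coords_node = NULL) {
  cfg <- model$config
  if (modality == "2d") {
    b <- build_batch2d(lapply(mols, `[[`, "g2d"), cfg)
    fwd_encode(tape, P, "enc2d", b, cfg, "2d")$pooled
  } else {
    b <- build_batch3d(lapply(mols, `[[`, "g3d"), cfg)
    fwd_encode(tape, P, "enc3d", b, cfg, "3d", coords = coords_node)$pooled
  }
}

#' Finetune a prediction head (and optionally the encoder) on labels
#'
#' Classification trains a linear logit head on the pooled embedding
#' (ROC-AUC metric); regression a 2-layer head (MAE metric); `forces` trains
#' the 2-layer head on molecular energies and evaluates per-atom forces as
#' the negative gradient of the predicted energy with respect to input
#' coordinates, obtained by differentiating through the full 3D encoder.
#'
#' @param mols list of paired entries.
#' @param labels numeric vector aligned with `mols` (energies for `forces`).
#' @param split list with `train` and `test` index vectors (may coincide for
#'   overfit checks).
#' @param model a [moltri_model()]; the encoder is updated unless `freeze`.
#' @param task `"classification"`, `"regression"` or `"forces"`.
#' @param modality encoder side used for the pooled embedding (3D for forces).
#' @param epochs full-batch Adam steps.
#' @param lr learning rate.
#' @param freeze if TRUE only the head is trained.
#' @param hidden hidden width of the regression head.
#' @param seed integer seed.
#' @return list with `metric` (named: `roc_auc` or `mae`), `predictions` on
#'   the test split, the trained `model` and head parameters. For `forces`,
#'   also `force_pred`/`force_metric` (per-atom cosine with the labels is up
#'   to the caller; see [predict_forces()]).
#' @export
finetune <- function(mols, labels, split, model,
                     task = c("classification", "regression", "forces"),
                     modality = NULL, epochs = 100L, lr = 1e-2,
                     freeze = FALSE, hidden = 32L, seed = 1L) {
  task <- match.arg(task)
  if (is.null(modality)) modality <- if (task == "classification") "2d" else "3d"
  stopifnot(length(labels) == length(mols))
  tr <- split$train; te <- split$test
  if (length(intersect(tr, te)) && !identical(sort(tr), sort(te))) {
    warning("train and test splits overlap")
  }
  if (task == "classification") {
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L) {
      stop("ROC-AUC undefined: split contains a single class")
    }
  }
  hp <- init_head_params(task, model$config$pool_dim, hidden, seed)
  # label standardization for the regression-type heads
  mu <- 0; sdv <- 1
  if (task != "classification") {
    mu <- mean(labels[tr]); sdv <- stats::sd(labels[tr])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
  }
  y_tr <- matrix(if (task == "classification") labels[tr] else
    (labels[tr] - mu) / sdv, ncol = 1L)
  pooled_frozen <- if (freeze) {
    fwd_pooled(NULL, model$ps$val, model, mols[tr], modality)
  }
  for (e in seq_len(epochs)) {
    tape <- ad_tape()
    P <- ps_leaves(tape, hp)
    if (!freeze) {
      Penc <- ps_leaves(tape, model$ps)
      for (nm in names(model$ps$val)) assign(nm, get(nm, Penc), envir = P)
      pooled <- fwd_pooled(tape, P, model, mols[tr], modality)
    } else {
      pooled <- ad_val(pooled_frozen)
    }
    out <- fwd_head(tape, P, task, pooled)
    loss <- if (task == "classification") {
      # mean binary cross-entropy via softplus: y*sp(-x) + (1-y)*sp(x)
      ad_mean(tape, ad_add(tape,
        ad_mul(tape, ad_softplus(tape, ad_affine(tape, out, -1)), y_tr),
        ad_mul(tape, ad_softplus(tape, out), 1 - y_tr)))
    } else {
      ad_mean(tape, ad_square(tape, ad_sub(tape, out, y_tr)))
    }
    ad_backward(tape, loss)
    adam_step(hp, ps_grads(hp, P), lr = lr)
    if (!freeze) {
      gen <- ps_grads(model$ps, P)
      adam_step(model$ps, gen[names(model$ps$val)], lr = lr / 10)
    }
  }
  pooled_te <- fwd_pooled(NULL, model$ps$val, model, mols[te], modality)
  pred <- as.numeric(ad_val(fwd_head(NULL, hp$val, task, pooled_te)))
  if (task != "classification") pred <- pred * sdv + mu
  metric <- if (task == "classification") {
    c(roc_auc = roc_auc(pred, labels[te]))
  } else {
    c(mae = mean(abs(pred - labels[te])))
  }
  list(metric = metric, predictions = pred, model = model, head = hp$val,
       task = task, modality = modality, label_scale = c(mu = mu, sd = sdv))
}

#' Predict per-atom forces from a trained energy head
#'
#' The predicted energy is the finetuned head on the pooled 3D embedding; the
#' force on each atom is minus the gradient of that energy with respect to the
#' atom's coordinates, computed by reverse-mode differentiation through the
#' distance map, the radial basis, the continuous-filter convolution and the
#' triangle blocks.
#'
#' @param mol a paired entry (needs `g3d`).
#' @param fit result of [finetune()] with `task = "forces"`.
#' @return n x 3 matrix of forces (label units).
#' @export
predict_forces <- function(mol, fit) {
  model <- fit$model
  tape <- ad_tape()
  coords <- ad_leaf(tape, mol$g3d$coords)
  pooled <- fwd_pooled(tape, model$ps$val, model, list(mol), "3d",
                       coords_node = coords)
  e <- fwd_head(tape, fit$head, "forces", pooled)
  ad_backward(tape, e)
  -coords$grad * fit$label_scale[["sd"]]
}

## ---- retrieval ---------------------------------------------------------------

#' Retrieve the nearest corpus molecules to a query by embedding cosine
#'
#' @param query a single entry (or `Graph2D`).
#' @param corpus list of entries.
#' @param model a [moltri_model()].
#' @param top_k number of hits to return.
#' @param modality embedding side (2D by default, as in topology-only
#'   retrieval).
#' @return data.frame with `rank`, `index`, `cosine`, sorted by descending
#'   cosine; ties broken by corpus index.
#' @export
retrieve <- function(query, corpus, model, top_k = 4L,
                     modality = c("2d", "3d")) {
  modality <- match.arg(modality)
  if (length(corpus) == 0L) stop("retrieval corpus is empty")
  emb <- predict_pooled(c(list(query), corpus), model, modality)
  q <- emb[1, ]
  M <- emb[-1, , drop = FALSE]
  cosine <- as.numeric(M %*% q) /
    (sqrt(rowSums(M^2)) * sqrt(sum(q^2)))
  ord <- order(-cosine, seq_along(cosine))
  k <- min(top_k, length(corpus))
  data.frame(rank = seq_len(k), index = ord[seq_len(k)],
             cosine = cosine[ord[seq_len(k)]])
}

## ---- circular fingerprints ---------------------------------------------------

ihash <- function(v) {
  h <- 11
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Hashed circular-substructure (ECFP-style) fingerprint
#'
#' Iterative neighborhood hashing of atom invariants (element, degree, formal
#' charge, aromaticity) out to `radius` bonds, folded onto `n_bits` bits.
#'
#' @param g2d a `Graph2D`.
#' @param radius neighborhood radius (default 2, i.e. ECFP4-like).
#' @param n_bits fingerprint length.
#' @return sorted integer vector of set bit positions (1-based).
#' @export
ecfp_fingerprint <- function(g2d, radius = 2L, n_bits = 2048L) {
  n <- g2d$n
  nbr <- neighbor_map(g2d)
  btype <- matrix(0L, n, n)
  if (length(g2d$bond_u)) btype[cbind(g2d$bond_u, g2d$bond_v)] <- g2d$bond_type
  inv <- vapply(seq_len(n), function(u) {
    ihash(c(match(g2d$elements[u], ELEMENT_VOCAB, nomatch = length(ELEMENT_VOCAB)),
            length(nbr[[u]]), g2d$charges[u], as.integer(g2d$aromatic[u])))
  }, 0)
  feats <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(u) {
      env <- sort(vapply(nbr[[u]], function(v) {
        ihash(c(btype[u, v], inv[v]))
      }, 0))
      ihash(c(r, inv[u], env))
    }, 0)
    feats <- c(feats, inv)
  }
  sort(unique(as.integer(feats %% n_bits) + 1L))
}

#' Tanimoto similarity between circular fingerprints
#'
#' `|F_a & F_b| / |F_a | F_b|` over the set bits; symmetric, in `[0, 1]`,
#' and 1 for identical molecules.
#'
#' @param a,b `Graph2D` objects.
#' @inheritParams ecfp_fingerprint
#' @export
ecfp_tanimoto <- function(a, b, radius = 2L, n_bits = 2048L) {
  fa <- ecfp_fingerprint(a, radius, n_bits)
  fb <- ecfp_fingerprint(b, radius, n_bits)
  length(intersect(fa, fb)) / length(union(fa, fb))
}
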
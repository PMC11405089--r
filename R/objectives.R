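# Contrastive and cross-modal edge-supervision objectives.
#
# The two edge objectives transfer information across modalities: a distogram
# head predicts discretized 3D distances from 2D edge embeddings, and a bond
# head predicts 2D bond classes (plus no-bond) from 3D pair embeddings. The
# node objective is an EBM-NCE discrimination between matched and in-batch
# deranged (noised sample, condition) pairs, with the condition entering the
# score-network trunk through a projection of the pooled embedding of the
# other modality. A symmetric InfoNCE over pooled embeddings is available as
# an optional batch-level term.

#' Softmax cross-entropy from logits
#'
#' @param logits n x k matrix.
#' @param labels integer class indices in `1..k`.
#' @param reduce `"mean"` (per-row average) or `"sum"`.
#' @return scalar loss (>= 0; zero only at one-hot-correct predictions).
#' @export
softmax_cross_entropy <- function(logits, labels, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  m <- apply(logits, 1L, max)
  ls <- logits - m - log(rowSums(exp(logits - m)))
  ce <- -ls[cbind(seq_along(labels), labels)]
  if (reduce == "mean") mean(ce) else sum(ce)
}

# Tape version of mean/sum softmax cross-entropy.
fwd_cross_entropy <- function(tape, logits, labels, reduce = "mean") {
  n <- nrow(ad_val(logits))
  k <- ncol(ad_val(logits))
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), labels)] <- 1
  ls <- ad_logsoftmax_rows(tape, logits)
  picked <- ad_sum(tape, ad_mul(tape, ls, onehot))
  ad_affine(tape, picked, mult = if (reduce == "mean") -1 / n else -1)
}

# Unordered pair table (u < v, global indices) for the 2D edge loss, with the
# true distance and the bonded-pair id (0 when non-bonded).
disto_pair_table <- function(mols, batch2, bonded_only) {
  ns <- vapply(mols, function(m) m$g2d$n, 1L)
  off <- cumsum(c(0L, utils::head(ns, -1L)))
  out <- NULL
  for (i in seq_along(mols)) {
    n <- ns[i]
    if (n < 2L) next
    eg <- expand.grid(u = seq_len(n), v = seq_len(n))
    eg <- eg[eg$u < eg$v, ]
    d <- mols[[i]]$g3d$dist[cbind(eg$u, eg$v)]
    tab <- data.frame(u = eg$u + off[i], v = eg$v + off[i], d = d)
    out <- rbind(out, tab)
  }
  if (is.null(out)) return(NULL)
  out$zid <- batch2$pid[cbind(out$u, out$v)]
  if (bonded_only) out <- out[out$zid > 0L, , drop = FALSE]
  out
}

fwd_edge_loss_2d <- function(tape, P, model, mols, state2 = NULL,
                             bonded_only = FALSE, reduce = "mean",
                             batch2 = NULL) {
  cfg <- model$config
  if (is.null(batch2)) batch2 <- build_batch2d(lapply(mols, `[[`, "g2d"), cfg)
  if (is.null(state2)) state2 <- fwd_encode(tape, P, "enc2d", batch2, cfg, "2d")
  for (i in seq_along(mols)) {
    if (is.null(mols[[i]]$g3d)) stop("edge_loss_2d requires a paired conformation for molecule ", i)
    if (mols[[i]]$g3d$n != mols[[i]]$g2d$n) {
      stop("atom count mismatch in molecule ", i, ": 2D ", mols[[i]]$g2d$n,
           " vs 3D ", mols[[i]]$g3d$n)
    }
  }
  tab <- disto_pair_table(mols, batch2, bonded_only)
  if (is.null(tab) || nrow(tab) == 0L) return(ad_leaf(NULL, matrix(0, 1L, 1L)))
  labels <- bin_distance(tab$d, model$binspec) + 1L
  hu <- ad_gather_rows(tape, state2$h, tab$u)
  hv <- ad_gather_rows(tape, state2$h, tab$v)
  zx <- ad_concat_rows(tape, list(state2$z, pget(P, "head.disto.null")))
  zid <- ifelse(tab$zid == 0L, batch2$pairs$n + 1L, tab$zid)
  zsel <- ad_gather_rows(tape, zx, zid)
  inp <- ad_concat_cols(tape, list(ad_add(tape, hu, hv), zsel))
  logits <- nn_linear(tape, P, "head.disto", inp)
  fwd_cross_entropy(tape, logits, labels, reduce)
}

fwd_edge_loss_3d <- function(tape, P, model, mols, state3 = NULL,
                             reduce = "mean", batch3 = NULL) {
  cfg <- model$config
  if (is.null(batch3)) batch3 <- build_batch3d(lapply(mols, `[[`, "g3d"), cfg)
  if (is.null(state3)) state3 <- fwd_encode(tape, P, "enc3d", batch3, cfg, "3d")
  for (i in seq_along(mols)) {
    if (is.null(mols[[i]]$g2d)) stop("edge_loss_3d requires a paired 2D graph for molecule ", i)
    if (mols[[i]]$g3d$n != mols[[i]]$g2d$n) {
      stop("atom count mismatch in molecule ", i, ": 2D ", mols[[i]]$g2d$n,
           " vs 3D ", mols[[i]]$g3d$n)
    }
  }
  sel <- which(batch3$pairs$u < batch3$pairs$v)
  if (length(sel) == 0L) return(ad_leaf(NULL, matrix(0, 1L, 1L)))
  ns <- vapply(mols, function(m) m$g2d$n, 1L)
  off <- cumsum(c(0L, utils::head(ns, -1L)))
  labels <- integer(length(sel))
  for (i in seq_along(mols)) {
    lab <- bond_labels(mols[[i]]$g2d)
    loc <- which(batch3$pairs$mol[sel] == i)
    labels[loc] <- lab[cbind(batch3$pairs$u[sel][loc] - off[i],
                             batch3$pairs$v[sel][loc] - off[i])]
  }
  zsel <- ad_gather_rows(tape, state3$z, sel)
  logits <- nn_linear(tape, P, "head.bond", zsel)
  fwd_cross_entropy(tape, logits, labels, reduce)
}

#' Distogram loss: predict discretized 3D distances from 2D edge embeddings
#'
#' For every heavy-atom pair (all unordered pairs by default; `bonded_only`
#' restricts to the bonded edge set, matching the printed normalizer), the
#' true pairwise distance is binned by the model's [bin_spec()] and compared
#' by cross-entropy with a linear head over `[h_u + h_v, z_uv]` (non-bonded
#' pairs use a learned null edge embedding).
#'
#' @param mols list of paired entries.
#' @param model a [moltri_model()].
#' @param bonded_only restrict the pair set to 2D bonds.
#' @param reduce `"mean"` (default, scale-stable) or `"sum"`.
#' @return scalar loss.
#' @export
edge_loss_2d <- function(mols, model, bonded_only = FALSE,
                         reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  as.numeric(ad_val(fwd_edge_loss_2d(NULL, model$ps$val, model, mols,
                                     bonded_only = bonded_only,
                                     reduce = reduce)))
}

#' Bond-class loss: predict 2D bond types (plus no-bond) from 3D embeddings
#'
#' Every unordered atom pair of the fully connected 3D graph gets a 5-class
#' label (single/double/triple/aromatic/no-bond) from the paired 2D graph; a
#' linear head over the 3D pair embedding is trained by cross-entropy.
#'
#' @inheritParams edge_loss_2d
#' @export
edge_loss_3d <- function(mols, model, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  as.numeric(ad_val(fwd_edge_loss_3d(NULL, model$ps$val, model, mols,
                                     reduce = reduce)))
}

## ---- node contrastive (EBM-NCE) ---------------------------------------------

# Random derangement of 1..n (no fixed point), deterministic per seed.
derangement <- function(n, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "derangement"))
  k <- sample.int(n - 1L, 1L)
  c((k + 1L):n, seq_len(k))  # cyclic shift: always fixed-point free
}

fwd_node_contrastive <- function(tape, P, model, mols, seed,
                                 pooled2 = NULL, pooled3 = NULL,
                                 batch3 = NULL) {
  K <- length(mols)
  if (K < 2L) {
    stop("node_contrastive_loss needs a batch of at least 2 molecules ",
         "(no mismatched pairs exist for a batch of 1)")
  }
  cfg <- model$config
  if (is.null(pooled2)) {
    b2 <- build_batch2d(lapply(mols, `[[`, "g2d"), cfg)
    pooled2 <- fwd_encode(tape, P, "enc2d", b2, cfg, "2d")$pooled
  }
  if (is.null(pooled3)) {
    b3 <- build_batch3d(lapply(mols, `[[`, "g3d"), cfg)
    pooled3 <- fwd_encode(tape, P, "enc3d", b3, cfg, "3d")$pooled
  }
  per <- derangement(K, seed)
  ## 3D-side term: noised conformation, 2D condition
  sch3 <- model$sched3d
  t3 <- sample_times(K, sch3, seed, "tc23")
  g3ds <- lapply(mols, `[[`, "g3d")
  if (is.null(batch3)) batch3 <- build_batch3d(g3ds, cfg)
  noised3 <- lapply(seq_len(K), function(i) {
    perturb_3d(g3ds[[i]], t3[i], sch3, seed = derive_seed(seed, paste0("c23.", i)))
  })
  xt <- do.call(rbind, lapply(noised3, `[[`, "x_t"))
  cond2 <- nn_linear(tape, P, "score23.condproj", pooled2)        # K x D_h
  cond_pos <- ad_gather_rows(tape, cond2, batch3$mol_id)
  cond_neg <- ad_gather_rows(tape, cond2, per[batch3$mol_id])
  d_pos <- fwd_score23(tape, P, "score23", xt, cond_pos, batch3, t3, sch3, cfg)$disc
  d_neg <- fwd_score23(tape, P, "score23", xt, cond_neg, batch3, t3, sch3, cfg)$disc
  # -1/2 E log sig(pos) - 1/2 E log(1 - sig(neg)), stable via softplus
  l3d <- ad_affine(tape,
                   ad_add(tape,
                          ad_mean(tape, ad_softplus(tape, ad_affine(tape, d_pos, -1))),
                          ad_mean(tape, ad_softplus(tape, d_neg))),
                   mult = 0.5)
  ## 2D-side term: noised relaxed 2D features, 3D condition
  sch2 <- model$sched2d
  t2 <- sample_times(K, sch2, seed, "tc32")
  g2ds <- lapply(mols, `[[`, "g2d")
  noised2 <- lapply(seq_len(K), function(i) {
    perturb_2d(g2ds[[i]], t2[i], sch2, seed = derive_seed(seed, paste0("c32.", i)))
  })
  Vt <- do.call(rbind, lapply(noised2, `[[`, "V_t"))
  Et <- do.call(rbind, lapply(noised2, `[[`, "E_t"))
  ns <- vapply(g2ds, function(g) g$n, 1L)
  mol_id2 <- rep(seq_len(K), ns)
  pair_mol2 <- rep(seq_len(K), vapply(g2ds, function(g) length(g$bond_u), 1L))
  cond3h <- nn_linear(tape, P, "score32.condproj", pooled3)
  cond3z <- nn_linear(tape, P, "score32.condprojz", pooled3)
  disc32 <- function(perm) {
    ch <- ad_gather_rows(tape, cond3h, perm[mol_id2])
    cz <- if (nrow(Et)) ad_gather_rows(tape, cond3z, perm[pair_mol2]) else NULL
    fwd_score32(tape, P, "score32", Vt, if (nrow(Et)) Et else NULL, ch, cz,
                mol_id2, pair_mol2, t2, sch2, K)$disc
  }
  d2_pos <- disc32(seq_len(K))
  d2_neg <- disc32(per)
  l2d <- ad_affine(tape,
                   ad_add(tape,
                          ad_mean(tape, ad_softplus(tape, ad_affine(tape, d2_pos, -1))),
                          ad_mean(tape, ad_softplus(tape, d2_neg))),
                   mult = 0.5)
  list(total = ad_add(tape, l2d, l3d), l2d = l2d, l3d = l3d)
}

#' Node-level EBM-NCE contrastive loss
#'
#' Per modality, a scalar discriminator head on the score network's pooled
#' trunk representation scores (noised sample, condition) pairs: matched pairs
#' are positives, in-batch deranged conditions are negatives, and the loss is
#' `-1/2 E[log sigmoid(D_pos)] - 1/2 E[log(1 - sigmoid(D_neg))]` summed over
#' the two modality terms. With zero discriminator logits each modality term
#' equals `log 2`; a perfectly separating discriminator drives it to 0.
#'
#' @inheritParams edge_loss_2d
#' @param seed integer seed (times, noise, derangement).
#' @return scalar; attributes `l2d`/`l3d` carry the per-modality terms.
#' @export
node_contrastive_loss <- function(mols, model, seed = 1L) {
  out <- fwd_node_contrastive(NULL, model$ps$val, model, mols, seed)
  structure(as.numeric(ad_val(out$total)),
            l2d = as.numeric(ad_val(out$l2d)),
            l3d = as.numeric(ad_val(out$l3d)))
}

## ---- batch-level InfoNCE ----------------------------------------------------

fwd_infomax <- function(tape, pooled2, pooled3, temperature = 0.1) {
  K <- nrow(ad_val(pooled2))
  normalize <- function(x) {
    n <- ad_sqrt(tape, ad_rowsums(tape, ad_square(tape, x)))
    ad_div(tape, x, ad_index_cols(tape, n, rep(1L, ncol(ad_val(x)))))
  }
  S <- ad_affine(tape, ad_matmul_t(tape, normalize(pooled2), normalize(pooled3)),
                 mult = 1 / temperature)
  diag_mask <- diag(1, K)
  nce <- function(logits) {
    ls <- ad_logsoftmax_rows(tape, logits)
    ad_affine(tape, ad_sum(tape, ad_mul(tape, ls, diag_mask)), mult = -1 / K)
  }
  ad_affine(tape, ad_add(tape, nce(S), nce(ad_transpose(tape, S))), mult = 0.5)
}

#' Symmetric InfoNCE over pooled 2D/3D embeddings
#'
#' Cosine similarities between all pooled embeddings in the batch; the
#' diagonal (paired) entries are positives and within-batch off-diagonal
#' entries are negatives, averaged over both softmax directions. With all
#' similarities equal the loss is `log K`.
#'
#' @param pooled2d,pooled3d K x D matrices, row i of each being the same
#'   molecule.
#' @param temperature softmax temperature.
#' @return scalar loss.
#' @export
gta_infomax_loss <- function(pooled2d, pooled3d, temperature = 0.1) {
  stopifnot(nrow(pooled2d) == nrow(pooled3d))
  if (nrow(pooled2d) < 2L) stop("infomax loss needs a batch of at least 2")
  as.numeric(ad_val(fwd_infomax(NULL, pooled2d, pooled3d, temperature)))
}

## ---- total objective ---------------------------------------------------------

#' Combine loss components into the overall training objective
#'
#' @param components named list (numeric scalars) with any of `L_node`,
#'   `L_edge_2D`, `L_edge_3D`, `L_2D3D`, `L_3D2D`, `L_infomax`; missing
#'   components count as 0.
#' @param weights a [loss_weights()].
#' @return scalar
#'   `alpha1 (eta1 L_node + eta2 (L_edge_2D + L_edge_3D)) + alpha2 L_2D3D +
#'    alpha3 L_3D2D + alpha4 L_infomax`.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, weights)
  g <- function(nm) if (is.null(components[[nm]])) 0 else as.numeric(components[[nm]])
  w <- weights
  w$alpha1 * (w$eta1 * g("L_node") + w$eta2 * (g("L_edge_2D") + g("L_edge_3D"))) +
    w$alpha2 * g("L_2D3D") + w$alpha3 * g("L_3D2D") + w$alpha4 * g("L_infomax")
}

# Combined tape forward over all enabled losses; encodes each modality once.
fwd_loss_bundle <- function(tape, P, model, mols, seed) {
  cfg <- model$config
  w <- model$weights
  b2 <- build_batch2d(lapply(mols, `[[`, "g2d"), cfg)
  b3 <- build_batch3d(lapply(mols, `[[`, "g3d"), cfg)
  st2 <- fwd_encode(tape, P, "enc2d", b2, cfg, "2d")
  st3 <- fwd_encode(tape, P, "enc3d", b3, cfg, "3d")
  comp <- list()
  nodes <- list()
  nodes$L_edge_2D <- fwd_edge_loss_2d(tape, P, model, mols, state2 = st2,
                                      batch2 = b2)
  nodes$L_edge_3D <- fwd_edge_loss_3d(tape, P, model, mols, state3 = st3,
                                      batch3 = b3)
  nc <- fwd_node_contrastive(tape, P, model, mols, seed,
                             pooled2 = st2$pooled, pooled3 = st3$pooled,
                             batch3 = b3)
  nodes$L_node <- nc$total
  nodes$L_2D3D <- fwd_loss_2d_to_3d(tape, P, model, mols, seed,
                                    cond_h = st2$h, batch3 = b3)
  # bonded-pair condition embeddings for the 2D-feature score network
  zidx <- b3$pid[cbind(b2$pairs$u, b2$pairs$v)]
  cond32 <- list(h = st3$h,
                 z = if (b2$pairs$n) ad_gather_rows(tape, st3$z, zidx) else NULL,
                 mol_id = b3$mol_id, pair_mol = b2$pairs$mol)
  nodes$L_3D2D <- fwd_loss_3d_to_2d(tape, P, model, mols, seed, cond = cond32)
  if (w$alpha4 > 0) {
    nodes$L_infomax <- fwd_infomax(tape, st2$pooled, st3$pooled, w$temperature)
  }
  # weighted sum on the tape
  total <- NULL
  addw <- function(total, nd, wt) {
    if (is.null(nd) || wt == 0) return(total)
    term <- ad_affine(tape, nd, mult = wt)
    if (is.null(total)) term else ad_add(tape, total, term)
  }
  total <- addw(total, nodes$L_node, w$alpha1 * w$eta1)
  total <- addw(total, nodes$L_edge_2D, w$alpha1 * w$eta2)
  total <- addw(total, nodes$L_edge_3D, w$alpha1 * w$eta2)
  total <- addw(total, nodes$L_2D3D, w$alpha2)
  total <- addw(total, nodes$L_3D2D, w$alpha3)
  total <- addw(total, nodes$L_infomax, w$alpha4)
  comp <- lapply(nodes, function(nd) as.numeric(ad_val(nd)))
  comp$L_node_2D <- as.numeric(ad_val(nc$l2d))
  comp$L_node_3D <- as.numeric(ad_val(nc$l3d))
  comp$L_total <- as.numeric(ad_val(total))
  list(total = total, components = comp)
}

#' Compute all loss components for a batch (no parameter update)
#'
#' @inheritParams edge_loss_2d
#' @param seed integer seed.
#' @return named list of scalar components including `L_total`.
#' @export
loss_bundle <- function(mols, model, seed = 1L) {
  fwd_loss_bundle(NULL, model$ps$val, model, mols, seed)$components
}
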
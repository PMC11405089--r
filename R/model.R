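# The full pretraining model: both encoders, both score networks, the edge
# prediction heads and the contrastive discriminator conditioning projections,
# in one flat parameter store driven by a single optimizer.

#' Loss weights for the overall training objective
#'
#' The total objective is
#' `L = alpha1 * (eta1 * L_node + eta2 * L_edge) + alpha2 * L_2D3D +
#'  alpha3 * L_3D2D + alpha4 * L_infomax`,
#' with `L_edge = L_edge_2D + L_edge_3D`. All weights default to 1 except the
#' optional batch-level InfoNCE term (`alpha4 = 0`); `temperature` is the
#' InfoNCE temperature.
#'
#' @param eta1,eta2 node/edge contrastive weights.
#' @param alpha1,alpha2,alpha3,alpha4 top-level term weights (non-negative).
#' @param temperature InfoNCE temperature.
#' @export
loss_weights <- function(eta1 = 1, eta2 = 1, alpha1 = 1, alpha2 = 1,
                         alpha3 = 1, alpha4 = 0, temperature = 0.1) {
  w <- list(eta1 = eta1, eta2 = eta2, alpha1 = alpha1, alpha2 = alpha2,
            alpha3 = alpha3, alpha4 = alpha4, temperature = temperature)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Construct the full pretraining model
#'
#' @param config an [encoder_config()] shared by both encoders.
#' @param seed integer seed for deterministic parameter initialization.
#' @param binspec a [bin_spec()] for the distogram head.
#' @param sched3d,sched2d [sde_schedule()]s for the 3D (VE) and 2D (VP)
#'   forward SDEs.
#' @param weights a [loss_weights()].
#' @return a `moltri_model`: parameter store plus configuration.
#' @export
moltri_model <- function(config = encoder_config(), seed = 1L,
                         binspec = bin_spec(),
                         sched3d = sde_schedule("ve"),
                         sched2d = sde_schedule("vp"),
                         weights = loss_weights()) {
  ps <- ps_new()
  init_encoder_params(ps, "enc2d", config, "2d", seed)
  init_encoder_params(ps, "enc3d", config, "3d", seed)
  init_score23_params(ps, "score23", config, seed)
  init_score32_params(ps, "score32", config, seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "init.heads"))
  # distogram head reads [h_u + h_v, z_uv-or-null]; bond head reads z^3D
  ps_add_linear(ps, "head.disto", config$D_h + config$D_z, binspec$n_bins)
  ps_add(ps, "head.disto.null", matrix(stats::rnorm(config$D_z, 0, 0.1), 1L))
  ps_add_linear(ps, "head.bond", config$D_z, length(PAIR_CLASSES))
  # pooled-condition projections feeding the contrastive discriminators
  ps_add_linear(ps, "score23.condproj", config$pool_dim, config$D_h)
  ps_add_linear(ps, "score32.condproj", config$pool_dim, config$D_h)
  ps_add_linear(ps, "score32.condprojz", config$pool_dim, config$D_z)
  m <- list(ps = ps, config = config, binspec = binspec,
            sched3d = sched3d, sched2d = sched2d, weights = weights,
            seed = as.integer(seed))
  class(m) <- "moltri_model"
  m
}

#' @export
print.moltri_model <- function(x, ...) {
  np <- sum(vapply(x$ps$val, length, 1L))
  cat("<moltri_model> ", length(x$ps$val), " parameter tensors, ",
      np, " parameters, D_h=", x$config$D_h, " D_z=", x$config$D_z,
      " blocks=", x$config$n_blocks, "\n", sep = "")
  invisible(x)
}

#' Encode a batch with the model's own parameters
#'
#' @param mols list of paired entries.
#' @param model a [moltri_model()].
#' @param modality `"2d"` or `"3d"`.
#' @return an `EmbeddingState`.
#' @export
model_encode <- function(mols, model, modality = c("2d", "3d")) {
  modality <- match.arg(modality)
  ps <- model$ps
  attr(ps, "config") <- model$config
  class(ps) <- "moltri_params"
  if (modality == "2d") gta2d_encode(mols, params = ps)
  else gta3d_encode(mols, params = ps)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: configuration, schedules, weights, all
#' parameter values, optimizer moments, step counter and seed.
#'
#' @param model a `moltri_model`.
#' @param path file path (RDS).
#' @param step training step stored alongside.
#' @export
save_checkpoint <- function(model, path, step = 0L) {
  obj <- list(config = model$config, binspec = model$binspec,
              sched3d_args = schedule_args(model$sched3d),
              sched2d_args = schedule_args(model$sched2d),
              weights = unclass(model$weights), seed = model$seed,
              step = as.integer(step),
              val = model$ps$val, adam_m = model$ps$adam_m,
              adam_v = model$ps$adam_v, adam_t = model$ps$adam_t)
  saveRDS(obj, path)
  invisible(path)
}

schedule_args <- function(sch) {
  sch[setdiff(names(sch), c("mean_coef", "std", "drift", "diffusion"))]
}

rebuild_schedule <- function(args) {
  if (args$kind == "ve") {
    sde_schedule("ve", sigma_min = args$sigma_min, sigma_max = args$sigma_max,
                 t_eps = args$t_eps)
  } else {
    sde_schedule("vp", beta_min = args$beta_min, beta_max = args$beta_max,
                 t_eps = args$t_eps)
  }
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  m <- moltri_model(config = cfg, seed = obj$seed, binspec = obj$binspec,
                    sched3d = rebuild_schedule(obj$sched3d_args),
                    sched2d = rebuild_schedule(obj$sched2d_args),
                    weights = do.call(loss_weights, obj$weights))
  if (!identical(sort(names(m$ps$val)), sort(names(obj$val)))) {
    bad <- c(setdiff(names(m$ps$val), names(obj$val)),
             setdiff(names(obj$val), names(m$ps$val)))
    stop("checkpoint/config mismatch in parameter field(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  m$ps$val <- obj$val
  m$ps$adam_m <- obj$adam_m
  m$ps$adam_v <- obj$adam_v
  m$ps$adam_t <- obj$adam_t
  attr(m, "step") <- obj$step
  m
}
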
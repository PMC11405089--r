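# Deterministic generator of paired 2D/3D toy molecules.
#
# The fixtures carry the statistical structure the cross-modal edge objectives
# assume: each bond type has a distinct mean length (with small Gaussian
# jitter), and non-bonded atoms are placed so their distances mostly exceed the
# distogram range. Chains are laid out as zig-zags with ~111 degree bond
# angles, rings as regular polygons with in-plane substituents; each molecule
# then receives a random rigid motion. Valence (C4/N3/O2, aromatic bonds
# counted 1.5) is respected by construction.

VALENCE_MAX <- c(C = 4, N = 3, O = 2)
BOND_ORDER_VAL <- c(1, 2, 3, 1.5)  # single, double, triple, aromatic

#' Specification for the synthetic fixture set
#'
#' Defaults encode the study conditions of the toy data: carbon-class mean
#' lengths of 1.54 (single), 1.34 (double) and 1.39 (aromatic) Angstrom, and a
#' per-bond jitter of 0.01 Angstrom - small enough that bond-type classes are
#' separable by length (the generator enforces `3 * sigma_len <` the minimum
#' gap between the sorted means).
#'
#' @param n_molecules number of molecules.
#' @param n_atoms integer range (min, max) of heavy-atom counts.
#' @param mean_length named numeric vector of mean bond lengths (Angstrom) for
#'   `single`, `double`, `aromatic`.
#' @param sigma_len Gaussian jitter s.d. on bond lengths (Angstrom).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @export
fixture_spec <- function(n_molecules = 40L,
                         n_atoms = c(3L, 12L),
                         mean_length = c(single = 1.54, double = 1.34,
                                         aromatic = 1.39),
                         sigma_len = 0.01,
                         seed = 1L) {
  stopifnot(n_molecules >= 1L, length(n_atoms) == 2L, n_atoms[1] >= 3L,
            n_atoms[2] >= n_atoms[1],
            all(c("single", "double", "aromatic") %in% names(mean_length)))
  gap <- min(diff(sort(mean_length)))
  if (3 * sigma_len >= gap) {
    stop("infeasible spec: 3*sigma_len (", 3 * sigma_len,
         ") must be below the minimum inter-mean gap (", gap,
         ") for bond-type classes to be separable")
  }
  bs <- bin_spec()
  if (any(mean_length < bs$lo | mean_length > bs$hi)) {
    stop("infeasible spec: mean lengths must lie within the default distogram range [",
         bs$lo, ", ", bs$hi, "] Angstrom")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_atoms = as.integer(n_atoms),
                 mean_length = mean_length, sigma_len = sigma_len,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

used_valence <- function(bonds, n) {
  v <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    o <- BOND_ORDER_VAL[bonds$type[i]]
    v[bonds$u[i]] <- v[bonds$u[i]] + o
    v[bonds$v[i]] <- v[bonds$v[i]] + o
  }
  v
}

sample_len <- function(spec, type) {
  mu <- switch(type, `1` = spec$mean_length[["single"]],
               `2` = spec$mean_length[["double"]],
               `4` = spec$mean_length[["aromatic"]])
  stats::rnorm(1L, mu, spec$sigma_len)
}

rigid_motion <- function(coords) {
  # random rotation via QR of a Gaussian matrix, det forced positive
  m <- matrix(stats::rnorm(9L), 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- stats::rnorm(3L, 0, 3)
  sweep(coords %*% q, 2L, shift, "+")
}

make_chain_molecule <- function(n, spec) {
  # backbone of nb atoms, k = n - nb single-bonded branch atoms
  k <- if (n >= 5L) sample(0:min(2L, n - 4L), 1L) else 0L
  nb <- n - k
  elements <- rep("C", n)
  # heteroatoms only at positions kept free of double bonds
  hetero <- which(stats::runif(nb) < 0.25)
  elements[hetero] <- sample(c("N", "O"), length(hetero), replace = TRUE)
  bonds <- data.frame(u = seq_len(nb - 1L), v = 2:nb, type = 1L)
  for (i in seq_len(nb - 1L)) {
    if (elements[i] == "C" && elements[i + 1L] == "C" && stats::runif(1L) < 0.3) {
      cand <- bonds
      cand$type[i] <- 2L
      if (all(used_valence(cand, n) <= VALENCE_MAX[elements])) bonds <- cand
    }
  }
  # place backbone as a zig-zag with ~111 degree angles
  beta <- (180 - 111) / 2 * pi / 180
  coords <- matrix(0, n, 3L)
  for (i in seq_len(nb - 1L)) {
    len <- sample_len(spec, as.character(bonds$type[i]))
    dir <- c(cos(beta), if (i %% 2L == 0L) sin(beta) else -sin(beta), 0)
    coords[i + 1L, ] <- coords[i, ] + len * dir
  }
  # attach branches to interior backbone atoms, out of plane
  if (k > 0L) {
    free <- function(b) {
      v <- used_valence(b, n)
      setdiff(which(v[seq_len(nb)] + 1 <= VALENCE_MAX[elements[seq_len(nb)]]), c(1L, nb))
    }
    side <- 1
    for (j in seq_len(k)) {
      a <- n - k + j
      host_pool <- free(bonds)
      if (length(host_pool) == 0L) { elements[a] <- "C"; host_pool <- 2L }
      host <- host_pool[sample.int(length(host_pool), 1L)]
      bonds <- rbind(bonds, data.frame(u = host, v = a, type = 1L))
      len <- sample_len(spec, "1")
      dir <- c(-0.25, 0, side * 0.97)
      dir <- dir / sqrt(sum(dir^2))
      coords[a, ] <- coords[host, ] + len * dir
      side <- -side
    }
  }
  list(elements = elements, bonds = bonds, coords = coords)
}

make_ring_molecule <- function(n, spec) {
  m <- if (n >= 6L && stats::runif(1L) < 0.7) 6L else 5L
  aromatic <- (m == 6L)
  ring_elem <- rep("C", m)
  if (aromatic && stats::runif(1L) < 0.3) ring_elem[sample.int(m, 1L)] <- "N"
  ring_order <- if (aromatic) 3 else 2  # valence used by the two ring bonds
  slots <- pmax(floor(VALENCE_MAX[ring_elem] - ring_order + 1e-9), 0)
  host_pool <- rep(seq_len(m), slots)
  n_sub <- min(n - m, length(host_pool))
  elements <- c(ring_elem,
                if (n_sub > 0L) sample(c("C", "N", "O"), n_sub, replace = TRUE))
  n_actual <- m + n_sub
  type <- if (aromatic) 4L else 1L
  bonds <- data.frame(u = seq_len(m), v = c(2:m, 1L), type = type)
  side <- sample_len(spec, as.character(type))
  R <- side / (2 * sin(pi / m))
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  coords <- matrix(0, n_actual, 3L)
  coords[seq_len(m), 1] <- R * cos(ang)
  coords[seq_len(m), 2] <- R * sin(ang)
  if (n_sub > 0L) {
    hosts <- if (length(host_pool) == 1L) host_pool else sample(host_pool, n_sub)
    taken <- integer(m)  # substituents already on each host
    for (j in seq_len(n_sub)) {
      a <- m + j
      h <- hosts[j]
      bonds <- rbind(bonds, data.frame(u = h, v = a, type = 1L))
      len <- sample_len(spec, "1")
      radial <- c(cos(ang[h]), sin(ang[h]), 0)
      dir <- if (taken[h] == 0L) radial else {
        d <- radial * 0.4 + c(0, 0, ifelse(taken[h] == 1L, 1, -1))
        d / sqrt(sum(d^2))
      }
      taken[h] <- taken[h] + 1L
      coords[a, ] <- coords[h, ] + len * dir
    }
  }
  list(elements = elements, bonds = bonds, coords = coords)
}

#' Generate a deterministic set of paired 2D/3D toy molecules
#'
#' Produces chemically plausible small graphs (chains, branched chains, 5/6
#' rings with substituents) whose bonded distances equal the bond type's mean
#' length plus Gaussian jitter, realized in 3D with tetrahedral-like angles so
#' non-bonded distances land at or beyond the top of the distogram range where
#' geometrically feasible. Fully deterministic per `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return list of entries with `g2d`, `g3d`, `name` (same shape as
#'   [read_molecules()] output).
#' @export
make_fixture_set <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, "make_fixture_set"))
  out <- vector("list", spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    n <- sample(spec$n_atoms[1]:spec$n_atoms[2], 1L)
    mk <- if (n >= 5L && stats::runif(1L) < 0.45) make_ring_molecule else make_chain_molecule
    mol <- mk(n, spec)
    coords <- rigid_motion(mol$coords)
    g2d <- graph2d(mol$elements, mol$bonds)
    g3d <- build_graph3d(coords, as.integer(ELEMENT_Z[mol$elements]))
    out[[i]] <- list(g2d = g2d, g3d = g3d, name = sprintf("fix%03d", i))
  }
  out
}

#' Property labels for fixture molecules
#'
#' Three label roles mirroring common downstream tasks: `classification` is a
#' ring-presence flag (separable from topology), `regression` is the sum of
#' bonded lengths (learnable from 3D), and `forces` are the analytic negative
#' gradient of a harmonic bond-energy toy, E = sum_bonds k (d_uv - d0_type)^2.
#'
#' @param fixtures list from [make_fixture_set()].
#' @param task one of `"classification"`, `"regression"`, `"forces"`.
#' @param seed integer seed (kept for interface symmetry; labels are
#'   deterministic functions of the fixtures).
#' @param k harmonic force constant (forces task), kcal/mol/A^2 scale toy.
#' @param d0 named equilibrium lengths per bond type; defaults to the
#'   [fixture_spec()] means.
#' @return for classification/regression, a data.frame with `index`, `name`,
#'   `label`; for forces, a list of n x 3 matrices (one per molecule).
#' @export
make_property_labels <- function(fixtures,
                                 task = c("classification", "regression", "forces"),
                                 seed = 1L, k = 1,
                                 d0 = c(single = 1.54, double = 1.34,
                                        aromatic = 1.39)) {
  task <- match.arg(task)
  if (task == "forces") {
    return(lapply(fixtures, function(m) harmonic_forces(m, k = k, d0 = d0)))
  }
  lab <- vapply(seq_along(fixtures), function(i) {
    m <- fixtures[[i]]
    bonds <- bond_table(m$g2d)
    if (task == "classification") {
      as.numeric(nrow(bonds) >= m$g2d$n)  # connected graph has a cycle iff |E| >= |V|
    } else {
      sum(m$g3d$dist[cbind(bonds$u, bonds$v)])
    }
  }, 0)
  data.frame(index = seq_along(fixtures),
             name = vapply(fixtures, function(m) m$name %||% "", ""),
             label = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic forces of the harmonic bond toy: F_a = -dE/dx_a.
harmonic_forces <- function(mol, k = 1,
                            d0 = c(single = 1.54, double = 1.34, aromatic = 1.39)) {
  g2d <- mol$g2d; g3d <- mol$g3d
  bonds <- bond_table(g2d)
  F <- matrix(0, g3d$n, 3L)
  if (nrow(bonds) == 0L) return(F)
  d0v <- unname(d0[c("single", "double", "triple", "aromatic")[bonds$type]])
  d0v[is.na(d0v)] <- 1.5
  for (i in seq_len(nrow(bonds))) {
    u <- bonds$u[i]; v <- bonds$v[i]
    dvec <- g3d$coords[u, ] - g3d$coords[v, ]
    d <- sqrt(sum(dvec^2))
    gmag <- 2 * k * (d - d0v[i]) / d  # dE/dd * dd/dx_u direction factor
    F[u, ] <- F[u, ] - gmag * dvec
    F[v, ] <- F[v, ] + gmag * dvec
  }
  F
}

# Harmonic bond-toy energy (used by finite-difference checks).
harmonic_energy <- function(mol, k = 1,
                            d0 = c(single = 1.54, double = 1.34, aromatic = 1.39),
                            coords = NULL) {
  g2d <- mol$g2d
  if (is.null(coords)) coords <- mol$g3d$coords
  bonds <- bond_table(g2d)
  if (nrow(bonds) == 0L) return(0)
  d0v <- unname(d0[c("single", "double", "triple", "aromatic")[bonds$type]])
  d0v[is.na(d0v)] <- 1.5
  d <- sqrt(rowSums((coords[bonds$u, , drop = FALSE] -
                     coords[bonds$v, , drop = FALSE])^2))
  sum(k * (d - d0v)^2)
}
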
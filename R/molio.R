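# Molecular containers and file I/O.
#
# A molecule is carried in two modalities: a 2D topological graph (typed atoms,
# typed bonds) and a 3D conformation (coordinates in Angstrom with the fully
# connected pairwise distance map). SDF is read through ChemmineR; SMILES is
# parsed via ChemmineR/ChemmineOB; XYZ is a trivial fixed layout parsed here.

ELEMENT_VOCAB <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "other")
BOND_CLASSES <- c("single", "double", "triple", "aromatic")
PAIR_CLASSES <- c(BOND_CLASSES, "nobond")

ELEMENT_Z <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
               Cl = 17L, Br = 35L, I = 53L)

element_from_z <- function(z) {
  nm <- names(ELEMENT_Z)[match(z, ELEMENT_Z)]
  ifelse(is.na(nm), "other", nm)
}

#' Construct a 2D topological molecular graph
#'
#' Nodes are typed atoms, edges are typed chemical bonds. Bonds are stored in
#' both directions so directed pair operations (e.g. directed triangle
#' attention) are expressible; the undirected bond list is recoverable as the
#' pairs with `u < v`.
#'
#' @param elements character vector of element symbols (one per atom).
#' @param bonds data.frame with integer columns `u`, `v` and column `type`
#'   (integer 1-4 or one of `"single"`, `"double"`, `"triple"`, `"aromatic"`),
#'   one row per undirected bond. May have zero rows.
#' @param charges integer formal charges per atom (default 0).
#' @return an object of class `Graph2D` with fields `n`, `elements`, `charges`,
#'   `aromatic` (per-atom flag), and directed bond vectors `bond_u`, `bond_v`,
#'   `bond_type`.
#' @export
graph2d <- function(elements, bonds = NULL, charges = NULL) {
  n <- length(elements)
  stopifnot(n >= 1L)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(u = integer(0), v = integer(0), type = integer(0))
  }
  type <- bonds$type
  if (is.character(type) || is.factor(type)) type <- match(as.character(type), BOND_CLASSES)
  type <- as.integer(type)
  u <- as.integer(bonds$u); v <- as.integer(bonds$v)
  if (any(u == v)) stop("self-loop bonds are not allowed")
  if (length(u) && (min(c(u, v)) < 1L || max(c(u, v)) > n)) {
    stop("bond indices out of range 1..", n)
  }
  if (any(is.na(type)) || (length(type) && any(type < 1L | type > 4L))) {
    stop("bond types must be 1-4 or one of: ", paste(BOND_CLASSES, collapse = ", "))
  }
  aromatic <- logical(n)
  aromatic[c(u[type == 4L], v[type == 4L])] <- TRUE
  g <- list(n = n,
            elements = as.character(elements),
            charges = as.integer(charges),
            aromatic = aromatic,
            bond_u = c(u, v),
            bond_v = c(v, u),
            bond_type = c(type, type))
  class(g) <- "Graph2D"
  g
}

#' @export
print.Graph2D <- function(x, ...) {
  cat("<Graph2D> ", x$n, " atoms, ", length(x$bond_u) / 2L, " bonds (",
      paste(unique(x$elements), collapse = ","), ")\n", sep = "")
  invisible(x)
}

# Adjacency lists N(u) over the bonded graph.
neighbor_map <- function(g2d) {
  out <- vector("list", g2d$n)
  for (i in seq_along(g2d$bond_u)) {
    u <- g2d$bond_u[i]
    out[[u]] <- c(out[[u]], g2d$bond_v[i])
  }
  lapply(out, function(x) sort(unique(x)))
}

# Undirected bond data.frame (u < v).
bond_table <- function(g2d) {
  keep <- g2d$bond_u < g2d$bond_v
  data.frame(u = g2d$bond_u[keep], v = g2d$bond_v[keep], type = g2d$bond_type[keep])
}

#' Construct a 3D conformation as a fully connected distance graph
#'
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param atomic_numbers integer atomic numbers (>= 1), one per atom.
#' @return an object of class `Graph3D` with fields `coords`, `z` and the full
#'   symmetric `dist` matrix (Angstrom, zero diagonal). No distance cutoff is
#'   applied: every atom pair is an edge of the 3D graph.
#' @export
build_graph3d <- function(coords, atomic_numbers) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L)
  bad <- which(!is.finite(rowSums(coords)))
  if (length(bad)) stop("non-finite coordinates at atom index ", bad[1])
  z <- as.integer(atomic_numbers)
  stopifnot(length(z) == nrow(coords), all(z >= 1L))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  g <- list(coords = coords, z = z, n = nrow(coords), dist = d)
  class(g) <- "Graph3D"
  g
}

#' @export
print.Graph3D <- function(x, ...) {
  cat("<Graph3D> ", x$n, " atoms, fully connected distance graph\n", sep = "")
  invisible(x)
}

## ---- distance discretization ----------------------------------------------

#' Distance bin specification for distogram labels
#'
#' Bins are left-closed, right-open, covering `[lo, hi)` in `n_bins` equal
#' widths; values below `lo` clamp into the first bin and values at or above
#' `hi` clamp into the last (absorbing end bins), so every non-negative
#' distance receives a label. Default: 32 bins over 1.0-2.4 Angstrom.
#'
#' @param lo,hi range in Angstrom, `lo < hi`.
#' @param n_bins number of bins (>= 2).
#' @export
bin_spec <- function(lo = 1.0, hi = 2.4, n_bins = 32L) {
  stopifnot(lo < hi, n_bins >= 2L)
  structure(list(lo = lo, hi = hi, n_bins = as.integer(n_bins),
                 width = (hi - lo) / n_bins),
            class = "bin_spec")
}

#' Discretize distances into distogram bins
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param spec a [bin_spec()].
#' @param one_hot if TRUE return a length(d) x n_bins one-hot matrix instead.
#' @return integer bin indices in `0 .. n_bins-1` (0-based; bin k covers
#'   `[lo + k*w, lo + (k+1)*w)`), or a one-hot matrix.
#' @export
bin_distance <- function(d, spec = bin_spec(), one_hot = FALSE) {
  stopifnot(all(d >= 0))
  k <- floor((d - spec$lo) / spec$width)
  k <- pmin(pmax(k, 0), spec$n_bins - 1L)
  k <- as.integer(k)
  if (!one_hot) return(k)
  m <- matrix(0, length(d), spec$n_bins)
  m[cbind(seq_along(d), k + 1L)] <- 1
  m
}

#' Bond-class labels for every atom pair
#'
#' Bonded pairs take their bond type from the 2D graph; every remaining pair of
#' the fully connected 3D graph is labelled `nobond`, giving a 5-class label
#' per ordered pair.
#'
#' @param g2d a [graph2d()] object.
#' @param g3d optional paired [build_graph3d()] conformation; if supplied its
#'   atom count must match.
#' @return n x n integer matrix with entries in 1..5 indexing
#'   `c("single","double","triple","aromatic","nobond")`; diagonal is NA.
#' @export
bond_labels <- function(g2d, g3d = NULL) {
  if (!is.null(g3d) && g3d$n != g2d$n) {
    stop("atom count mismatch: 2D graph has ", g2d$n, " atoms, 3D has ", g3d$n)
  }
  n <- g2d$n
  lab <- matrix(5L, n, n)
  diag(lab) <- NA_integer_
  if (length(g2d$bond_u)) {
    lab[cbind(g2d$bond_u, g2d$bond_v)] <- g2d$bond_type
  }
  attr(lab, "classes") <- PAIR_CLASSES
  lab
}

## ---- file reading ----------------------------------------------------------

sdf_record_to_pair <- function(sdf, hydrogens = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(u = integer(0), v = integer(0), type = integer(0))
  } else {
    bonds <- data.frame(u = as.integer(bb[, 1]), v = as.integer(bb[, 2]),
                        type = as.integer(bb[, 3]))
  }
  if (!hydrogens) {
    keep <- elements != "H"
    idx <- cumsum(keep)
    bonds <- bonds[keep[bonds$u] & keep[bonds$v], , drop = FALSE]
    bonds$u <- idx[bonds$u]; bonds$v <- idx[bonds$v]
    elements <- elements[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  if (length(elements) == 0L) stop("record has no atoms after hydrogen removal")
  g2d <- graph2d(elements, bonds)
  z <- ELEMENT_Z[elements]
  z[is.na(z)] <- 0L
  g3d <- build_graph3d(coords, pmax(as.integer(z), 1L))
  list(g2d = g2d, g3d = g3d)
}

read_sdf_records <- function(path, hydrogens = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    return(structure(list(), parse_report = empty_parse_report()))
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L || ends[length(ends)] < length(lines)) {
    ends <- c(ends, length(lines))
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  failures <- data.frame(index = integer(0), reason = character(0))
  rec_i <- 0L
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    if (all(!nzchar(trimws(setdiff(rec, "$$$$"))))) next
    rec_i <- rec_i + 1L
    name <- trimws(rec[1])
    pair <- tryCatch({
      tf <- tempfile(fileext = ".sdf")
      on.exit(unlink(tf), add = TRUE)
      if (!any(grepl("^\\$\\$\\$\\$", rec))) rec <- c(rec, "$$$$")
      writeLines(rec, tf)
      s <- suppressWarnings(ChemmineR::read.SDFset(tf))
      if (length(s) != 1L || !ChemmineR::validSDF(s)) stop("invalid SDF record")
      sdf_record_to_pair(s[[1]], hydrogens = hydrogens)
    }, error = function(e) e)
    if (inherits(pair, "error")) {
      warning("skipping unparseable SDF record ", rec_i, ": ",
              conditionMessage(pair), call. = FALSE)
      failures <- rbind(failures,
                        data.frame(index = rec_i, reason = conditionMessage(pair)))
    } else {
      pair$name <- if (nzchar(name)) name else paste0("mol", rec_i)
      out[[length(out) + 1L]] <- pair
    }
  }
  structure(out, parse_report = make_parse_report(rec_i, failures))
}

empty_parse_report <- function() {
  list(n_records = 0L, n_parsed = 0L, n_failed = 0L,
       failures = data.frame(index = integer(0), reason = character(0)))
}

make_parse_report <- function(n_records, failures) {
  list(n_records = n_records, n_parsed = n_records - nrow(failures),
       n_failed = nrow(failures), failures = failures)
}

read_smiles_file <- function(path, hydrogens = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  failures <- data.frame(index = integer(0), reason = character(0))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    smi <- trimws(parts[1])
    nm <- if (length(parts) > 1L) trimws(parts[2]) else paste0("mol", i)
    g <- tryCatch({
      s <- suppressWarnings(ChemmineR::smiles2sdf(smi))
      sdf_record_to_pair(s[[1]], hydrogens = hydrogens)$g2d
    }, error = function(e) e)
    if (inherits(g, "error")) {
      warning("skipping unparseable SMILES line ", i, ": ",
              conditionMessage(g), call. = FALSE)
      failures <- rbind(failures,
                        data.frame(index = i, reason = conditionMessage(g)))
    } else {
      out[[length(out) + 1L]] <- list(g2d = g, g3d = NULL, name = nm)
    }
  }
  structure(out, parse_report = make_parse_report(length(lines), failures))
}

read_xyz_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  failures <- data.frame(index = integer(0), reason = character(0))
  i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    rec <- rec + 1L
    res <- tryCatch({
      n <- as.integer(trimws(lines[i]))
      if (is.na(n) || n < 1L) stop("bad atom count line")
      rows <- lines[(i + 2L):(i + 1L + n)]
      tok <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(x) x[1:4]))
      coords <- matrix(as.numeric(tok[, 2:4]), ncol = 3L)
      elem <- tok[, 1]
      z <- ELEMENT_Z[elem]
      z[is.na(z)] <- 1L
      list(g = build_graph3d(coords, as.integer(z)), used = n + 2L)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping unparseable XYZ record ", rec, ": ",
              conditionMessage(res), call. = FALSE)
      failures <- rbind(failures,
                        data.frame(index = rec, reason = conditionMessage(res)))
      i <- i + 1L
      while (i <= length(lines) && is.na(suppressWarnings(as.integer(trimws(lines[i]))))) {
        i <- i + 1L
      }
    } else {
      out[[length(out) + 1L]] <- list(g2d = NULL, g3d = res$g, name = paste0("mol", rec))
      i <- i + res$used
    }
  }
  structure(out, parse_report = make_parse_report(rec, failures))
}

#' Read molecules from SDF, SMILES or XYZ files
#'
#' SDF records (with coordinates) yield paired 2D graph + 3D conformation
#' entries; SMILES yields 2D graphs only; XYZ yields bare conformations.
#' Unparseable records are skipped with a warning and counted in the parse
#' report attached as `attr(x, "parse_report")`; an empty file gives an empty
#' list. Molecule order is preserved.
#'
#' @param path file path.
#' @param format one of `"sdf"`, `"smiles"`, `"xyz"`.
#' @param hydrogens keep explicit hydrogens (default FALSE: heavy-atom graphs).
#' @return list of entries, each a list with elements `g2d` (`Graph2D` or
#'   NULL), `g3d` (`Graph3D` or NULL) and `name`.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles", "xyz"),
                           hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         sdf = read_sdf_records(path, hydrogens = hydrogens),
         smiles = read_smiles_file(path, hydrogens = hydrogens),
         xyz = read_xyz_file(path))
}

## ---- file writing ----------------------------------------------------------

#' Write paired molecules to an SDF (V2000) file
#'
#' @param mols list of entries as returned by [read_molecules()] or
#'   [make_fixture_set()] (each with `g2d` and `g3d`).
#' @param path output file path.
#' @export
write_sdf <- function(mols, path) {
  out <- character(0)
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    g2d <- m$g2d; g3d <- m$g3d
    stopifnot(!is.null(g2d), !is.null(g3d))
    bonds <- bond_table(g2d)
    nm <- if (!is.null(m$name)) m$name else paste0("mol", i)
    rec <- c(nm, "  moltri", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     g2d$n, nrow(bonds)))
    for (a in seq_len(g2d$n)) {
      rec <- c(rec, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            g3d$coords[a, 1], g3d$coords[a, 2], g3d$coords[a, 3],
                            g2d$elements[a]))
    }
    if (nrow(bonds)) {
      rec <- c(rec, sprintf("%3d%3d%3d  0  0  0  0", bonds$u, bonds$v, bonds$type))
    }
    rec <- c(rec, "M  END", "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

write_xyz <- function(mols, path) {
  out <- character(0)
  for (m in mols) {
    g3d <- m$g3d
    elem <- if (!is.null(m$g2d)) m$g2d$elements else element_from_z(g3d$z)
    out <- c(out, as.character(g3d$n), if (!is.null(m$name)) m$name else "",
             sprintf("%-3s %12.6f %12.6f %12.6f",
                     elem, g3d$coords[, 1], g3d$coords[, 2], g3d$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

## ---- scaffolds and splits --------------------------------------------------

# Bemis-Murcko scaffold atom set: iteratively prune degree-1 atoms.
murcko_atoms <- function(g2d) {
  bonds <- bond_table(g2d)
  alive <- rep(TRUE, g2d$n)
  repeat {
    deg <- integer(g2d$n)
    keep <- alive[bonds$u] & alive[bonds$v]
    if (any(keep)) {
      tb <- table(factor(c(bonds$u[keep], bonds$v[keep]), levels = seq_len(g2d$n)))
      deg <- as.integer(tb)
    }
    leaves <- which(alive & deg <= 1L)
    if (length(leaves) == 0L) break
    alive[leaves] <- FALSE
    if (!any(alive)) break
  }
  which(alive)
}

#' Bemis-Murcko scaffold key of a 2D graph
#'
#' The scaffold is the molecule with all terminal (degree-1) atoms iteratively
#' removed: ring systems plus linkers. The returned key is a canonical string
#' (exact up to colored-graph isomorphism, computed with BLISS canonical
#' labelling on an edge-subdivided colored graph), so two molecules share a key
#' iff they share a scaffold. Acyclic molecules all map to the empty scaffold
#' `""`.
#'
#' @param g2d a [graph2d()] object.
#' @return character scaffold key.
#' @export
murcko_scaffold_key <- function(g2d) {
  atoms <- murcko_atoms(g2d)
  if (length(atoms) == 0L) return("")
  idx <- match(seq_len(g2d$n), atoms)
  bonds <- bond_table(g2d)
  bonds <- bonds[!is.na(idx[bonds$u]) & !is.na(idx[bonds$v]), , drop = FALSE]
  na <- length(atoms)
  nb <- nrow(bonds)
  # colored graph: atom vertices colored by element, one subdivision vertex per
  # bond colored by bond type (so edge colors are captured exactly)
  colors <- c(match(g2d$elements[atoms], ELEMENT_VOCAB, nomatch = length(ELEMENT_VOCAB)),
              length(ELEMENT_VOCAB) + bonds$type)
  edges <- rbind(cbind(idx[bonds$u], na + seq_len(nb)),
                 cbind(idx[bonds$v], na + seq_len(nb)))
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  cp <- igraph::canonical_permutation(g, colors = colors)
  perm <- cp$labeling  # old id -> canonical id
  canon_colors <- integer(na + nb)
  canon_colors[perm] <- colors
  el <- igraph::as_edgelist(g)
  ce <- cbind(perm[el[, 1]], perm[el[, 2]])
  ce <- t(apply(ce, 1L, sort))
  ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
  paste0(paste(canon_colors, collapse = ","), "|",
         paste(ce[, 1], ce[, 2], sep = "-", collapse = ","))
}

#' Scaffold-based train/validation/test split
#'
#' Molecules sharing a Bemis-Murcko scaffold never straddle splits. Scaffold
#' groups are sorted by descending size (ties shuffled deterministically by
#' `seed`) and filled greedily into train, then validation, then test until
#' each reaches its target size.
#'
#' @param mols list of `Graph2D` objects or paired entries with a `g2d` field.
#' @param ratios three positive fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer seed controlling tie-breaking.
#' @return list with integer index vectors `train`, `valid`, `test` forming a
#'   partition of `seq_along(mols)`.
#' @export
scaffold_split <- function(mols, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9)
  g2ds <- lapply(mols, function(m) if (inherits(m, "Graph2D")) m else m$g2d)
  keys <- vapply(g2ds, murcko_scaffold_key, "")
  groups <- split(seq_along(mols), keys)
  if (length(groups) < 3L) {
    warning("fewer distinct scaffolds (", length(groups),
            ") than splits; some splits will be empty")
  }
  sizes <- vapply(groups, length, 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "scaffold_split"))
  ord <- order(-sizes, sample.int(length(groups)))
  groups <- groups[ord]
  n <- length(mols)
  target <- c(train = ratios[1] * n, valid = ratios[2] * n, test = ratios[3] * n)
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (g in groups) {
    if (length(out$train) < target["train"]) {
      out$train <- c(out$train, g)
    } else if (length(out$valid) < target["valid"]) {
      out$valid <- c(out$valid, g)
    } else {
      out$test <- c(out$test, g)
    }
  }
  lapply(out, sort)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Write or read split index files (JSON lists of 0-based indices)
#'
#' @param split list with `train`/`valid`/`test` 1-based index vectors.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(lapply(split, function(i) i - 1L), path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE),
         function(i) as.integer(i) + 1L)
}

#' Read a CSV label table
#'
#' Labels are matched to molecules by a `smiles` column when present, otherwise
#' by row order (index-aligned).
#'
#' @param path CSV path.
#' @export
read_label_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
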
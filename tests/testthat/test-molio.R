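# Molecular containers, file round trips, distance binning, bond labels and
# scaffold splitting.

test_that("graph2d validates bonds and symmetrizes directions", {
  g <- graph2d(c("C", "C", "O"), data.frame(u = c(1, 2), v = c(2, 3), type = 1L))
  expect_equal(length(g$bond_u), 4L)  # both directions stored
  expect_setequal(paste(g$bond_u, g$bond_v), c("1 2", "2 1", "2 3", "3 2"))
  expect_error(graph2d("C", data.frame(u = 1, v = 1, type = 1L)), "self-loop")
  expect_error(graph2d(c("C", "C"), data.frame(u = 1, v = 3, type = 1L)),
               "out of range")
})

test_that("build_graph3d produces a consistent full distance map", {
  g <- build_graph3d(rbind(c(0, 0, 0), c(0, 0, 1.5)), c(6L, 8L))
  expect_equal(g$dist[1, 2], 1.5)
  expect_equal(g$dist[2, 1], 1.5)
  expect_equal(diag(g$dist), c(0, 0))

  set.seed(3)
  coords <- matrix(rnorm(12), 4L)
  g <- build_graph3d(coords, rep(6L, 4))
  # brute-force double-loop oracle
  ref <- matrix(0, 4, 4)
  for (u in 1:4) for (v in 1:4) ref[u, v] <- sqrt(sum((coords[u, ] - coords[v, ])^2))
  expect_equal(g$dist, ref, tolerance = 1e-12)

  # isometry: rigid rotation leaves the distance map unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g2 <- build_graph3d(coords %*% R, rep(6L, 4))
  expect_lt(max(abs(g2$dist - g$dist)), 1e-9)

  bad <- coords; bad[3, 1] <- NaN
  expect_error(build_graph3d(bad, rep(6L, 4)), "atom index 3")
})

test_that("bin_distance follows the left-closed clamped convention", {
  spec <- bin_spec(1.0, 2.4, 32L)
  expect_equal(spec$width, 1.4 / 32)
  expect_equal(bin_distance(1.0, spec), 0L)   # lower boundary
  expect_equal(bin_distance(3.0, spec), 31L)  # clamps above
  expect_equal(bin_distance(0.2, spec), 0L)   # clamps below
  expect_equal(bin_distance(1.7, spec), 16L)  # exact boundary goes up
  # monotone, and exactly n_bins distinct outputs reachable
  d <- seq(0, 5, by = 0.001)
  b <- bin_distance(d, spec)
  expect_true(all(diff(b) >= 0))
  expect_equal(length(unique(b)), 32L)
  oh <- bin_distance(c(1.0, 1.7), spec, one_hot = TRUE)
  expect_equal(which(oh[2, ] == 1), 17L)  # 0-based bin 16
  expect_equal(rowSums(oh), c(1, 1))
})

test_that("bond_labels covers every pair with bond types plus no-bond", {
  eth <- ethanol_entry()
  lab <- bond_labels(eth$g2d, eth$g3d)
  up <- lab[upper.tri(lab)]
  expect_equal(sum(up == 1), 2L)  # two single bonds
  expect_equal(sum(up == 5), 1L)  # one no-bond pair
  expect_equal(length(up), 3L)    # n(n-1)/2 labels

  single <- graph2d("C")
  expect_equal(sum(!is.na(bond_labels(single))), 0L)

  benz <- benzene_entry()
  labb <- bond_labels(benz$g2d, benz$g3d)
  upb <- labb[upper.tri(labb)]
  expect_equal(sum(upb == 4), 6L)   # aromatic ring bonds
  expect_equal(sum(upb == 5), 9L)   # remaining pairs of the 6-cycle
  # count of bonded labels equals the undirected edge count, generally
  g <- random_graph2d(7)
  labr <- bond_labels(g)
  expect_equal(sum(labr[upper.tri(labr)] != 5), length(g$bond_u) / 2)

  expect_error(bond_labels(eth$g2d, benz$g3d), "mismatch.*3.*6")
})

test_that("SDF write/read round trip preserves graphs and coordinates", {
  fx <- small_fixtures()
  path <- tempfile(fileext = ".sdf")
  write_sdf(fx, path)
  back <- read_molecules(path, "sdf")
  expect_equal(length(back), length(fx))
  for (i in seq_along(fx)) {
    expect_equal(back[[i]]$g2d$elements, fx[[i]]$g2d$elements)
    expect_equal(bond_table(back[[i]]$g2d), bond_table(fx[[i]]$g2d))
    expect_lt(max(abs(back[[i]]$g3d$coords - fx[[i]]$g3d$coords)), 1e-4)
  }
  rep <- attr(back, "parse_report")
  expect_equal(rep$n_failed, 0L)
})

test_that("corrupt SDF records are skipped and counted; empty file is empty", {
  fx <- small_fixtures()[1:3]
  path <- tempfile(fileext = ".sdf")
  write_sdf(fx, path)
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  # mangle the counts line of the second record
  lines[ends[1] + 4L] <- "garbage counts line"
  writeLines(lines, path)
  expect_warning(back <- read_molecules(path, "sdf"), "skipping")
  expect_equal(length(back), 2L)
  rep <- attr(back, "parse_report")
  expect_equal(rep$n_failed, 1L)
  expect_equal(rep$failures$index, 2L)

  empty <- tempfile(fileext = ".sdf")
  writeLines(character(0), empty)
  expect_equal(length(read_molecules(empty, "sdf")), 0L)
})

test_that("SMILES parsing yields heavy-atom 2D graphs", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "CC=C"), path)
  out <- read_molecules(path, "smiles")
  expect_equal(length(out), 2L)
  g <- out[[1]]$g2d
  expect_equal(g$n, 3L)
  expect_equal(nrow(bond_table(g)), 2L)  # 4 directed entries
  expect_equal(length(g$bond_u), 4L)
  expect_true(all(bond_table(g)$type == 1L))
  expect_null(out[[1]]$g3d)
  expect_equal(out[[1]]$name, "ethanol")
  expect_equal(sort(bond_table(out[[2]]$g2d)$type), c(1L, 2L))
})

test_that("XYZ files read as bare conformations", {
  fx <- small_fixtures()[1:2]
  path <- tempfile(fileext = ".xyz")
  moltri:::write_xyz(fx, path)
  out <- read_molecules(path, "xyz")
  expect_equal(length(out), 2L)
  expect_null(out[[1]]$g2d)
  expect_lt(max(abs(out[[1]]$g3d$coords - fx[[1]]$g3d$coords)), 1e-5)
  expect_equal(out[[2]]$g3d$z, fx[[2]]$g3d$z)
})

test_that("Murcko scaffolds prune side chains and identify shared cores", {
  benz <- benzene_entry()$g2d
  # toluene-like: benzene plus one substituent
  tol <- graph2d(c(rep("C", 6), "C"),
                 rbind(data.frame(u = 1:6, v = c(2:6, 1), type = 4L),
                       data.frame(u = 1, v = 7, type = 1L)))
  expect_identical(murcko_scaffold_key(benz), murcko_scaffold_key(tol))
  chain <- ethanol_entry()$g2d
  expect_identical(murcko_scaffold_key(chain), "")
  ring5 <- graph2d(rep("C", 5), data.frame(u = 1:5, v = c(2:5, 1), type = 1L))
  expect_false(identical(murcko_scaffold_key(ring5), murcko_scaffold_key(benz)))
  # relabeled copy shares the scaffold key (canonical form)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L, 7L)
  tolp <- moltri:::permute_graph2d(tol, perm)
  expect_identical(murcko_scaffold_key(tolp), murcko_scaffold_key(tol))
})

ring_mol <- function(n) {
  graph2d(rep("C", n), data.frame(u = 1:n, v = c(2:n, 1), type = 1L))
}

test_that("scaffold_split fills train first and respects scaffold groups", {
  mols <- lapply(3:12, ring_mol)  # 10 molecules, 10 distinct scaffolds
  sp <- scaffold_split(mols, c(0.8, 0.1, 0.1), seed = 4L)
  expect_equal(lengths(sp), c(train = 8L, valid = 1L, test = 1L))
  # partition
  expect_setequal(unlist(sp), 1:10)
  expect_equal(sum(lengths(sp)), 10L)
  # determinism
  sp2 <- scaffold_split(mols, c(0.8, 0.1, 0.1), seed = 4L)
  expect_identical(sp, sp2)
  # same scaffold never straddles splits
  dup <- c(lapply(3:6, ring_mol), lapply(rep(5, 4), ring_mol))
  spd <- scaffold_split(dup, c(0.5, 0.25, 0.25), seed = 1L)
  grp5 <- c(3L, 5:8)  # indices of the 5-ring scaffold group
  inside <- vapply(spd, function(ix) length(intersect(ix, grp5)), 1L)
  expect_equal(sum(inside > 0), 1L)
  # single scaffold: everything lands in train with a warning
  expect_warning(spo <- scaffold_split(lapply(rep(6, 5), ring_mol),
                                       seed = 2L), "fewer distinct scaffolds")
  expect_equal(length(spo$train), 5L)
  expect_equal(length(spo$valid), 0L)
})

test_that("split files round trip through JSON", {
  sp <- list(train = 1:8, valid = 9L, test = 10L)
  path <- tempfile(fileext = ".json")
  write_split(sp, path)
  expect_equal(read_split(path), sp)
})
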
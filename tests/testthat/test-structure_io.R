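test_that("a hand-written PDB fixture is parsed with coordinates intact", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "N", "GLY", "A", 1, 1.234, -2.5, 3.75, elem = "N"),
    atom_rec(2, "CA", "GLY", "A", 1, 2.001, -1.2, 4.125),
    atom_rec(3, "C", "GLY", "A", 1, 3.5, 0, 5)))
  st <- read_structure(tf)
  expect_s3_class(st, "enm_structure")
  expect_equal(n_atoms(st), 3)
  expect_equal(st$atoms$x, c(1.234, 2.001, 3.500))
  expect_equal(st$atoms$y, c(-2.500, -1.200, 0.000))
  expect_equal(st$atoms$name, c("N", "CA", "C"))
  expect_false(any(st$atoms$is_hetero))
})

test_that("altloc resolution follows the policy, highest occupancy wins", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    atom_rec(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "B"),
    atom_rec(3, "CA", "ALA", "A", 2, 5, 0, 0)))
  hi <- read_structure(tf, altloc_policy = "highest_occupancy")
  expect_equal(n_atoms(hi), 2)
  expect_equal(hi$atoms$occ[1], 0.6)   # the B alternate, listed second
  expect_equal(hi$atoms$x[1], 1)
  # occupancy tie: first listed wins
  tft <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tft, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, alt = "A"),
    atom_rec(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "B"),
    atom_rec(3, "CA", "ALA", "A", 2, 5, 0, 0)))
  tie <- read_structure(tft, altloc_policy = "highest_occupancy")
  expect_equal(tie$atoms$x[1], 0)
  # "first" policy keeps the first listed alternate
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf2, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.3, alt = "A"),
    atom_rec(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.7, alt = "B"),
    atom_rec(3, "CA", "ALA", "A", 2, 5, 0, 0)))
  fi <- read_structure(tf2, altloc_policy = "first")
  expect_equal(fi$atoms$occ[1], 0.3)
})

test_that("hydrogens are dropped, hetero groups retained and flagged", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_rec(2, "HA", "ALA", "A", 1, 0.5, 0.5, 0, elem = "H"),
    atom_rec(3, "FE", "HEM", "A", 90, 9, 0, 0, elem = "FE", type = "HETATM"),
    atom_rec(4, "O", "HOH", "A", 99, 20, 0, 0, elem = "O", type = "HETATM")))
  st <- read_structure(tf)
  expect_equal(n_atoms(st), 2)
  expect_equal(st$atoms$is_hetero, c(FALSE, TRUE))
  expect_equal(st$atoms$resid[2], "HEM")
})

test_that("write/read round trip preserves coordinates and atom order", {
  st <- make_two_domain_dumbbell(10)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, tf)
  st2 <- read_structure(tf)
  expect_equal(n_atoms(st2), n_atoms(st))
  expect_equal(st2$atoms$resno, st$atoms$resno)
  xyz1 <- as.matrix(st$atoms[, c("x", "y", "z")])
  xyz2 <- as.matrix(st2$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(xyz1 - xyz2)), 5.1e-4)   # PDB three-decimal precision
  # a second round trip is exact
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st2, tf2)
  st3 <- read_structure(tf2)
  expect_identical(st3$atoms[, c("x", "y", "z")], st2$atoms[, c("x", "y", "z")])
})

test_that("CRYST1 metadata survives the round trip", {
  st <- make_helix(8)
  st$unit_cell <- c(140.17, 140.17, 119.1, 90, 90, 120)
  st$space_group <- "P 32 2 1"
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, tf)
  st2 <- read_structure(tf)
  expect_equal(st2$unit_cell, st$unit_cell, tolerance = 1e-6)
  expect_equal(st2$space_group, "P 32 2 1")
})

test_that("symmetry expansion: identity superposes, operator count multiplies atoms", {
  st <- make_helix(9)
  st$unit_cell <- c(50, 50, 60, 90, 90, 120)
  st$space_group <- "P 32 2 1"
  idc <- apply_symmetry(st, operators = symmetry_operators("P 1"))
  expect_equal(as.matrix(idc$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]), tolerance = 1e-12)
  all6 <- apply_symmetry(st)
  expect_equal(n_atoms(all6), 6 * n_atoms(st))
  expect_equal(length(unique(all6$atoms$chain)), 6)
})

test_that("an operator followed by its inverse restores coordinates", {
  st <- make_helix(11)
  st$unit_cell <- c(47, 47, 61, 90, 90, 120)
  st$space_group <- "P 32 2 1"
  ops <- symmetry_operators("P 32 2 1")
  for (k in c(2, 4, 6)) {
    fwd <- apply_symmetry(st, operators = list(ops[[k]]))
    back <- apply_symmetry(fwd, operators = list(invert_operator(ops[[k]])))
    dev <- max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                     as.matrix(st$atoms[, c("x", "y", "z")])))
    expect_lt(dev, 1e-6)
  }
})

test_that("operator rotations are orthogonal in the orthogonal frame", {
  cell <- c(47, 47, 61, 90, 90, 120)
  M <- enmaflex:::orthogonalization_matrix(cell)
  for (op in symmetry_operators("P 32 2 1")) {
    R <- M %*% op$rot %*% solve(M)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
    expect_equal(abs(det(R)), 1, tolerance = 1e-10)
  }
})

test_that("missing unit cell raises a configuration error", {
  expect_error(apply_symmetry(make_helix(5)), "unit cell")
})

test_that("node selection schemes count nodes as specified", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  recs <- list()
  for (i in 1:5) {
    recs[[length(recs) + 1]] <- atom_rec(3 * i - 2, "N", "ALA", "A", i,
                                         3.8 * i, 0, 0, elem = "N")
    recs[[length(recs) + 1]] <- atom_rec(3 * i - 1, "CA", "ALA", "A", i,
                                         3.8 * i + 1, 1, 0)
    recs[[length(recs) + 1]] <- atom_rec(3 * i, "C", "ALA", "A", i,
                                         3.8 * i + 2, 0, 0)
  }
  write_pdb_lines(tf, recs)
  st <- read_structure(tf)
  expect_equal(n_nodes(select_nodes(st, "calpha_plus_hetero")), 5)
  expect_equal(n_nodes(select_nodes(st, "all_heavy")), 15)
})

test_that("hetero heavy atoms all become nodes in C-alpha mode", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_rec(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    atom_rec(3, "FE", "HEM", "A", 90, 2, 3, 0, elem = "FE", type = "HETATM"),
    atom_rec(4, "NA", "HEM", "A", 90, 3, 4, 0, elem = "N", type = "HETATM")))
  nd <- select_nodes(read_structure(tf), "calpha_plus_hetero")
  expect_equal(n_nodes(nd), 4)
  expect_equal(sum(nd$info$is_hetero), 2)
})

test_that("a residue without CA is skipped with a warning", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_rec(2, "N", "GLY", "A", 2, 3.8, 0, 0, elem = "N"),
    atom_rec(3, "CA", "ALA", "A", 3, 7.6, 0, 0)))
  expect_warning(nd <- select_nodes(read_structure(tf)), "no CA")
  expect_equal(n_nodes(nd), 2)
})

test_that("layer assignment follows the r<=15 / 15<r<=20 / r>20 convention and partitions nodes", {
  # substrate at the origin, residues at controlled radii
  tf <- withr::local_tempfile(fileext = ".pdb")
  radii <- c(5, 14.9, 15.0, 15.1, 19.9, 20.0, 20.1, 30)
  recs <- list(atom_rec(1, "C1", "ASD", "S", 600, 0, 0, 0, type = "HETATM"))
  for (i in seq_along(radii))
    recs[[i + 1]] <- atom_rec(i + 1, "CA", "ALA", "A", i, radii[i], 0, 0)
  write_pdb_lines(tf, recs)
  st <- read_structure(tf)
  nd <- select_nodes(st)
  spec <- region_spec(list(substrate = list(resid = "ASD")))
  asg <- assign_regions(st, nd, spec)
  prot <- which(!nd$info$is_hetero)
  expect_equal(asg$layer[prot][match(seq_along(radii), nd$info$resno[prot])],
               c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L))
  # layers partition all nodes
  expect_false(any(is.na(asg$layer)))
  expect_equal(sum(table(asg$layer)), n_nodes(nd))
})

test_that("catalytic-cleft fallback selects residues near the substrate", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(tf, list(
    atom_rec(1, "C1", "ASD", "S", 600, 0, 0, 0, type = "HETATM"),
    atom_rec(2, "CA", "ALA", "A", 1, 4.0, 0, 0),   # within 4.5
    atom_rec(3, "CA", "ALA", "A", 2, 8.0, 0, 0)))  # outside
  st <- read_structure(tf)
  nd <- select_nodes(st)
  spec <- region_spec(list(substrate = list(resid = "ASD"),
                           catalytic_cleft = list()))
  asg <- assign_regions(st, nd, spec)
  cleft_res <- nd$info$resno[asg$regions[, "catalytic_cleft"]]
  expect_equal(cleft_res, 1)
})

test_that("charge census counts acidic/basic residues and the heme moiety", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  resids <- c("ASP", "ASP", "GLU", "LYS", "ARG", "HIS", "ALA")
  recs <- lapply(seq_along(resids), function(i)
    atom_rec(i, "CA", resids[i], "A", i, 4 * i, 0, 0))
  recs[[8]] <- atom_rec(8, "FE", "HEM", "A", 90, 0, 5, 0, elem = "FE",
                        type = "HETATM")
  write_pdb_lines(tf, recs)
  st <- read_structure(tf)
  cc <- charge_census(st, list(resno = c(1:7, 90)))
  expect_equal(cc$n_acidic, 3)
  expect_equal(cc$n_basic, 2)          # His excluded by default
  expect_true(cc$include_heme)
  cc_his <- charge_census(st, list(resno = c(1:7, 90)), include_his = TRUE)
  expect_equal(cc_his$n_basic, 3)
  empty <- charge_census(st, list(resno = 999))
  expect_equal(unlist(empty[c("n_acidic", "n_basic")]),
               c(n_acidic = 0L, n_basic = 0L))
  expect_false(empty$include_heme)
})

test_that("region spec YAML round trip resolves selectors", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("heme:", "  resid: HEM", "substrate:", "  resid: ASD",
               "access_channel:",
               "  resno: [192, 217, 218]", "layer_radii: [15, 20]"), tf)
  spec <- read_region_spec(tf)
  expect_s3_class(spec, "region_spec")
  expect_equal(spec$layer_radii, c(15, 20))
  expect_equal(spec$regions$access_channel$resno, c(192, 217, 218))
})

test_that("the shipped aromatase region config matches the published site lists", {
  cfgf <- system.file("extdata", "aromatase_regions.yaml",
                      package = "enmaflex")
  expect_true(nzchar(cfgf))
  spec <- read_region_spec(cfgf)
  expect_equal(length(spec$regions$access_channel$resno), 20)
  expect_equal(length(spec$regions$e_site$resno), 9)
  expect_equal(length(spec$regions$p_site$resno), 6)
  expect_equal(spec$layer_radii, c(15, 20))
})
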
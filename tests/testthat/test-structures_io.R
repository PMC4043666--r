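test_that("a minimal two-atom molecule round-trips through SDF and XYZ", {
  mol <- molecule("scl", c("S", "Cl"), rbind(c(0, 0, 0), c(2, 0, 0)),
                  data.frame(i = 1L, j = 2L, order = 1L))
  for (fmt in c("sdf", "xyz")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_structure(mol, path, fmt)
    back <- suppressWarnings(suppressMessages(read_structure(path)))
    expect_equal(back$elements, c("S", "Cl"))
    expect_equal(nrow(back$bonds), 1L)
    expect_equal(unname(geometric_distances(back)[1, 2]), 2.0,
                 tolerance = 1e-6)
    expect_lt(max(abs(back$coords - mol$coords)), 1e-4)
  }
})

test_that("generated molecules survive an SDF round trip to 1e-4 Angstrom", {
  for (seed in c(11, 12)) {
    mol <- gen_toy_molecule(seed)
    path <- tempfile(fileext = ".sdf")
    write_structure(mol, path)
    back <- read_structure(path)
    expect_equal(back$elements, mol$elements)
    expect_equal(back$bonds[order(back$bonds$i, back$bonds$j), c("i", "j")],
                 mol$bonds[order(mol$bonds$i, mol$bonds$j), c("i", "j")],
                 ignore_attr = TRUE)
    expect_lt(max(abs(back$coords - mol$coords)), 1e-4)
  }
})

test_that("xyz bond perception recovers methane's four C-H bonds", {
  # tetrahedral methane, C-H 1.09 A; covalent-radius oracle:
  # r(C) + r(H) + 0.4 = 0.76 + 0.31 + 0.4 = 1.47 >= 1.09, H..H 1.78 > 1.02
  h <- 1.09 / sqrt(3)
  coords <- rbind(c(0, 0, 0), c(h, h, h), c(h, -h, -h), c(-h, h, -h),
                  c(-h, -h, h))
  path <- tempfile(fileext = ".xyz")
  writeLines(c("5", "methane",
               sprintf("%s %f %f %f", c("C", "H", "H", "H", "H"),
                       coords[, 1], coords[, 2], coords[, 3])), path)
  mol <- read_structure(path)
  expect_equal(nrow(mol$bonds), 4L)
  expect_true(all(mol$bonds$i == 1L | mol$bonds$j == 1L))
})

test_that("malformed structure files raise parse errors, 2D SDF warns", {
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("three", "oops", "C 0 0 0"), bad)
  expect_error(read_structure(bad), "not an atom count")
  bad2 <- tempfile(fileext = ".xyz")
  writeLines(c("2", "", "C 0 0 0", "C 1.5 zz 0"), bad2)
  expect_error(read_structure(bad2), "non-numeric")
  flat <- molecule("flat", rep("C", 6), cbind(1.4 * cos(1:6), 1.4 * sin(1:6), 0),
                   data.frame(i = 1:5, j = 2:6, order = 1L))
  p <- tempfile(fileext = ".sdf")
  write_structure(flat, p)
  expect_warning(read_structure(p), "2D")
})

test_that("molecule validation rejects broken invariants", {
  expect_error(
    molecule("clash", c("C", "C"), rbind(c(0, 0, 0), c(0.3, 0, 0)),
             data.frame(i = 1L, j = 2L, order = 1L)),
    "0.5 Angstrom")
  expect_error(
    molecule("disc", c("C", "C", "C"),
             rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 5, 5)),
             data.frame(i = 1L, j = 2L, order = 1L)),
    "disconnected")
  expect_error(
    molecule("elem", c("C", "Xx"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
             data.frame(i = 1L, j = 2L, order = 1L)),
    "unsupported element")
})

test_that("topological distances match the BFS oracle and known cases", {
  chain <- make_chain(8)
  d <- topological_distances(chain)
  expect_equal(d[1, 8], 7L)
  expect_equal(max(topological_distances(make_ring6())), 3L)
  for (seed in c(21, 22)) {
    mol <- gen_toy_molecule(seed)
    d <- topological_distances(mol)
    expect_equal(unname(d), unname(bfs_distances(mol)), ignore_attr = TRUE)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0L))
    adj <- d == 1L
    for (k in seq_len(nrow(mol$bonds))) {
      expect_true(adj[mol$bonds$i[k], mol$bonds$j[k]])
    }
  }
})

test_that("disconnected graphs are reported with their components", {
  mol <- molecule("ok", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                  data.frame(i = 1L, j = 2L, order = 1L))
  mol$bonds <- mol$bonds[0, ]
  expect_error(topological_distances(mol), "disconnected")
})

test_that("geometric distances are rigid-motion invariant", {
  mol <- gen_toy_molecule(31)
  g0 <- geometric_distances(mol)
  g1 <- geometric_distances(apply_rigid(mol, 99))
  expect_lt(max(abs(g0 - g1)), 1e-9)
  tri <- molecule("tri", rep("C", 3),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.5 * sqrt(3) / 2, 0)),
                  data.frame(i = c(1, 2, 3), j = c(2, 3, 1), order = 1L))
  g <- geometric_distances(tri)
  expect_equal(unname(g[upper.tri(g)]), rep(1.5, 3), tolerance = 1e-12)
})

test_that("flip_torsion drives the dihedral and preserves internals", {
  mol <- make_anti_chain()
  expect_equal(measure_dihedral(mol, 1, 2, 3, 4), 180, tolerance = 1e-9)
  spec <- torsion_spec(1, 2, 3, 4, 0)
  syn <- flip_torsion(mol, spec)
  expect_lt(abs(measure_dihedral(syn, 1, 2, 3, 4)), 1e-6)
  # topology unchanged, bond lengths unchanged
  expect_equal(topological_distances(syn), topological_distances(mol))
  bl <- function(m) sqrt(rowSums((m$coords[m$bonds$i, ] -
                                  m$coords[m$bonds$j, ])^2))
  expect_equal(bl(syn), bl(mol), tolerance = 1e-9)
  # the 1-4 distance strictly changes for a 180 -> 0 flip
  expect_gt(abs(geometric_distances(mol)[1, 4] -
                geometric_distances(syn)[1, 4]), 0.1)
})

test_that("flip_torsion toggles the isomer tag and hits arbitrary targets", {
  mol <- gen_toy_molecule(41)
  ts <- attr(mol, "torsion")
  expect_equal(mol$isomer, "trans")
  for (target in c(0, 60, -120)) {
    out <- flip_torsion(mol, torsion_spec(ts$a, ts$b, ts$c, ts$d, target))
    got <- measure_dihedral(out, ts$a, ts$b, ts$c, ts$d)
    expect_lt(min(abs(got - target), abs(got - target + 360),
                  abs(got - target - 360)), 1e-6)
    expect_equal(out$isomer, "cis")
  }
})

test_that("flip_torsion rejects ring bonds and unbonded paths", {
  ring <- make_ring6()
  expect_error(flip_torsion(ring, torsion_spec(1, 2, 3, 4, 0)), "ring")
  chain <- make_chain(5)
  expect_error(flip_torsion(chain, torsion_spec(1, 2, 4, 5, 0)),
               "not bonded")
})

test_that("flip_torsion commutes with rigid motions", {
  mol <- gen_toy_molecule(51)
  ts <- attr(mol, "torsion")
  spec <- torsion_spec(ts$a, ts$b, ts$c, ts$d, 0)
  flipped_then_moved <- apply_rigid(flip_torsion(mol, spec), 7)
  moved_then_flipped <- flip_torsion(apply_rigid(mol, 7), spec)
  expect_lt(max(abs(geometric_distances(flipped_then_moved) -
                    geometric_distances(moved_then_flipped))), 1e-8)
})
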
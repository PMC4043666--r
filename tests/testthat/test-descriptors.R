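test_that("center_coordinates zeroes the centroid and is idempotent", {
  mol <- gen_toy_molecule(61)
  cc <- center_coordinates(mol)
  expect_lt(max(abs(colMeans(cc))), 1e-12)
  expect_equal(center_coordinates(cc), cc, tolerance = 1e-14)
  shifted <- mol
  shifted$coords <- sweep(mol$coords, 2, c(5, 5, 5), `+`)
  expect_equal(center_coordinates(shifted), cc, tolerance = 1e-12)
})

test_that("influence matrix of a regular tetrahedron matches closed form", {
  # vertices (1,1,1),(1,-1,-1),(-1,1,-1),(-1,-1,1): M'M = 4I, H = MM'/4
  m <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  H <- influence_matrix(m)
  expect_equal(unname(diag(H)), rep(0.75, 4), tolerance = 1e-12)
  expect_equal(H[1, 2], -0.25, tolerance = 1e-12)
})

test_that("influence matrix invariants hold for generated molecules", {
  for (seed in c(71, 72, 73)) {
    H <- influence_matrix(center_coordinates(gen_toy_molecule(seed)))
    expect_lt(max(abs(H %*% H - H)), 1e-9)           # idempotent
    expect_lt(abs(sum(diag(H)) - 3), 1e-9)           # rank 3 geometry
    expect_true(all(diag(H) >= -1e-12 & diag(H) <= 1 + 1e-12))
    expect_lt(max(abs(H - t(H))), 1e-12)
  }
  # planar square -> rank 2
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, -1, 0), c(-1, 1, 0))
  expect_equal(sum(diag(influence_matrix(sq))), 2, tolerance = 1e-9)
  # collinear -> rank 1
  ln <- cbind(1:4, 0, 0)
  expect_equal(sum(diag(influence_matrix(center_coordinates(ln)))), 1,
               tolerance = 1e-9)
  expect_error(influence_matrix(matrix(0, 3, 3)), "coincident")
})

test_that("GETAWAY H matches the brute-force pair-loop oracle", {
  scheme <- weight_scheme()
  chain <- make_chain(4, c("C", "N", "O", "S"))
  for (lag in 0:3) {
    expect_equal(getaway_h(chain, scheme, lag),
                 brute_getaway_h(chain, scheme, lag), tolerance = 1e-12)
  }
  mol <- gen_toy_molecule(81)
  for (lag in c(1, 3, 6)) {
    expect_equal(getaway_h(mol, scheme, lag),
                 brute_getaway_h(mol, scheme, lag), tolerance = 1e-12)
  }
  # lag beyond the topological diameter -> 0
  expect_identical(getaway_h(chain, scheme, 9), 0)
})

test_that("GETAWAY R matches its oracle; max variant bounded by sum", {
  scheme <- weight_scheme()
  mol <- gen_toy_molecule(82)
  for (lag in c(1, 2, 5, 7)) {
    expect_equal(getaway_r(mol, scheme, lag, "sum"),
                 brute_getaway_r(mol, scheme, lag, "sum"), tolerance = 1e-12)
    expect_equal(getaway_r_max(mol, scheme, lag),
                 brute_getaway_r(mol, scheme, lag, "max"), tolerance = 1e-12)
    expect_lte(getaway_r_max(mol, scheme, lag),
               getaway_r(mol, scheme, lag, "sum") + 1e-12)
  }
  # a single pair at the lag: sum and max coincide (two-atom fragment
  # bonded at distance 1)
  two <- molecule("two", c("S", "Cl"), rbind(c(0, 0, 0), c(2, 0, 0)),
                  data.frame(i = 1L, j = 2L, order = 1L))
  expect_equal(getaway_r(two, scheme, 1, "sum"),
               getaway_r_max(two, scheme, 1), tolerance = 1e-12)
})

test_that("3D descriptors are invariant under rigid motion and reindexing", {
  scheme <- weight_scheme()
  mol <- gen_toy_molecule(83)
  perm <- with_seed(9, sample(n_atoms(mol)))
  alt <- apply_rigid(permute_molecule(mol, perm), 5)
  for (lag in c(2, 4, 6)) {
    expect_equal(getaway_h(mol, scheme, lag), getaway_h(alt, scheme, lag),
                 tolerance = 1e-9)
    expect_equal(getaway_r_max(mol, scheme, lag),
                 getaway_r_max(alt, scheme, lag), tolerance = 1e-9)
  }
  expect_equal(geom_pair_sum(mol, "S", "Cl"), geom_pair_sum(alt, "S", "Cl"),
               tolerance = 1e-9)
  expect_equal(cats2d(mol), cats2d(alt))
})

test_that("torsion-flipped pairs: CATS2D identical, 3D descriptors differ", {
  scheme <- weight_scheme()
  for (seed in c(91, 92)) {
    tr <- gen_toy_molecule(seed)
    ts <- attr(tr, "torsion")
    ci <- flip_torsion(tr, torsion_spec(ts$a, ts$b, ts$c, ts$d, 0))
    expect_identical(cats2d(tr), cats2d(ci))
    h_tr <- vapply(1:8, function(k) getaway_h(tr, scheme, k), 0)
    h_ci <- vapply(1:8, function(k) getaway_h(ci, scheme, k), 0)
    g_tr <- geom_pair_sum(tr, "S", "Cl")
    g_ci <- geom_pair_sum(ci, "S", "Cl")
    expect_gt(max(abs(h_tr - h_ci), abs(g_tr - g_ci)), 1e-6)
  }
})

test_that("CATS2D pharmacophore counts match the enumeration oracle", {
  # HO-C-C-C-C-C-C-CH3: donor O, lipophilic terminal C at path length 7
  n <- 8
  coords <- cbind(1.5 * seq_len(n), 0.3 * sin(1.7 * seq_len(n)),
                  0.2 * cos(2.3 * seq_len(n)))
  coords <- rbind(coords, coords[1, ] + c(-0.6, 0.8, 0))   # H on O
  mol <- molecule("oh-chain", c("O", rep("C", 7), "H"), coords,
                  data.frame(i = c(1:7, 1L), j = c(2:8, 9L), order = 1L))
  v <- cats2d(mol)
  expect_equal(unname(v["CATS2D_07_DL"]), brute_cats(mol, 7, "D", "L"))
  expect_gte(v[["CATS2D_07_DL"]], 1L)
  for (nm in names(v)) {
    lag <- as.integer(substr(nm, 8, 9))
    pair <- substr(nm, 11, 12)
    expect_identical(unname(v[nm]),
                     brute_cats(mol, lag, substr(pair, 1, 1),
                                substr(pair, 2, 2)))
  }
})

test_that("a molecule without N-H/O-H donors has zero donor pairs", {
  chain <- make_chain(6, c("C", "C", "O", "C", "Cl", "C"))
  v <- cats2d(chain)
  expect_true(all(v[grep("_D", names(v))] == 0L))
  expect_gt(sum(v), 0L)   # acceptor/lipophilic pairs still counted
})

test_that("geometric pair sums are additive and vanish when absent", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3.5, 0))
  mol <- molecule("scl2", c("S", "Cl", "Cl"), coords,
                  data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
  expect_equal(geom_pair_sum(mol, "S", "Cl"), 5.5, tolerance = 1e-12)
  expect_identical(geom_pair_sum(mol, "S", "Br"), 0)
  expect_equal(geom_pair_sum(mol, "Cl", "Cl"),
               unname(geometric_distances(mol)[2, 3]), tolerance = 1e-12)
})

test_that("descriptor tables are deterministic and order-stable", {
  mols <- gen_isomer_series(5, n_compounds = 3, drop_cis_for = NULL)
  t1 <- compute_descriptor_table(mols)
  t2 <- compute_descriptor_table(mols)
  expect_identical(t1, t2)
  t3 <- compute_descriptor_table(rev(mols))
  expect_identical(t3$species, rev(t1$species))
  reord <- t3[match(t1$species, t3$species), ]
  rownames(reord) <- NULL
  expect_equal(reord, t1)
})

test_that("isomer screening keeps 3D columns that differ, never CATS2D", {
  mols <- gen_isomer_series(6, n_compounds = 3, drop_cis_for = NULL)
  tab <- compute_descriptor_table(mols)
  pairs <- data.frame(cis = paste0(1:3, "-cis"), trans = paste0(1:3, "-trans"))
  sel <- screen_isomer_differentiating(tab, pairs)
  expect_gt(length(sel), 0L)
  expect_false(any(startsWith(sel, "CATS2D_")))
  # monotone in tol: infinite threshold empties the selection
  expect_length(screen_isomer_differentiating(tab, pairs, tol = Inf), 0L)
  # identical rows select nothing
  tab2 <- tab
  for (cn in descriptor_columns(tab2)) tab2[[cn]] <- tab2[[cn]][1]
  expect_length(screen_isomer_differentiating(tab2, pairs), 0L)
  expect_error(screen_isomer_differentiating(tab, pairs[0, ]), "no isomer")
})

test_that("descriptor tables round-trip through CSV with exotic names", {
  mols <- gen_isomer_series(7, n_compounds = 2, drop_cis_for = NULL)
  tab <- compute_descriptor_table(mols)
  path <- tempfile(fileext = ".csv")
  write_descriptor_table(tab, path)
  back <- read_descriptor_table(path)
  expect_identical(names(back), names(tab))
  expect_equal(back[["G(S..Cl)"]], tab[["G(S..Cl)"]], tolerance = 1e-12)
})
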
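# Fixture builders and independent oracles shared across the suite.

# Linear-ish chain molecule: n atoms along x with a gentle fixed zigzag
# in y/z so the geometry has full rank; consecutive atoms bonded.
make_chain <- function(n, elements = rep("C", n), spacing = 1.5) {
  i <- seq_len(n)
  coords <- cbind(spacing * i,
                  0.3 * sin(1.7 * i),
                  0.2 * cos(2.3 * i))
  bonds <- data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
  molecule("chain", elements, coords, bonds)
}

# Butane-like 4-atom chain with an exact 180-degree dihedral.
make_anti_chain <- function() {
  coords <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0))
  molecule("anti", rep("C", 4), coords,
           data.frame(i = 1:3, j = 2:4, order = 1L))
}

# Benzene-like hexagon of carbons (side 1.4 A) in the xy plane.
make_ring6 <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  molecule("ring", rep("C", 6), cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
           data.frame(i = 1:6, j = c(2:6, 1L), order = 1L))
}

# Per-source breadth-first-search shortest-path oracle.
bfs_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- lapply(seq_len(n), function(i)
    c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i]))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Brute-force GETAWAY oracles: explicit double loop over atom pairs.
brute_getaway_h <- function(mol, scheme, lag) {
  H <- influence_matrix(center_coordinates(mol))
  topo <- topological_distances(mol)
  w <- unname(scheme$weights[mol$elements])
  total <- 0
  n <- n_atoms(mol)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (topo[i, j] == lag) total <- total + max(H[i, j], 0) * w[i] * w[j]
  }
  total
}

brute_getaway_r <- function(mol, scheme, lag, variant = "sum") {
  H <- influence_matrix(center_coordinates(mol))
  topo <- topological_distances(mol)
  geo <- geometric_distances(mol)
  w <- unname(scheme$weights[mol$elements])
  terms <- c()
  n <- n_atoms(mol)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (topo[i, j] == lag) {
      terms <- c(terms, sqrt(H[i, i] * H[j, j]) / geo[i, j] * w[i] * w[j])
    }
  }
  if (!length(terms)) return(0)
  if (variant == "sum") sum(terms) else max(terms)
}

# Brute-force CATS2D oracle for one pair type: enumerate heavy pairs.
brute_cats <- function(mol, lag, t1, t2) {
  topo <- topological_distances(mol)
  types <- qsrriso:::.ppp_types(mol)
  heavy <- which(mol$elements != "H")
  if (lag == 0) {
    return(sum(vapply(types[heavy],
                      function(tt) t1 %in% tt && t2 %in% tt, TRUE)))
  }
  cnt <- 0L
  for (a in seq_along(heavy)) for (b in seq_len(a - 1L)) {
    i <- heavy[a]; j <- heavy[b]
    if (topo[i, j] == lag &&
        ((t1 %in% types[[i]] && t2 %in% types[[j]]) ||
         (t2 %in% types[[i]] && t1 %in% types[[j]]))) cnt <- cnt + 1L
  }
  cnt
}

# Random rigid motion (proper rotation + translation), deterministic.
rigid_motion <- function(coords, seed) {
  rot <- with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  shift <- with_seed(seed + 1L, rnorm(3, sd = 5))
  sweep(coords %*% rot, 2, shift, `+`)
}

apply_rigid <- function(mol, seed) {
  mol$coords <- rigid_motion(mol$coords, seed)
  mol
}

# Reindex atoms by a permutation (bonds follow).
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  out <- mol
  out$elements <- mol$elements[perm]
  out$coords <- mol$coords[perm, , drop = FALSE]
  out$bonds$i <- inv[mol$bonds$i]
  out$bonds$j <- inv[mol$bonds$j]
  out
}
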
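#' @importFrom stats dist setNames coef lm pf pt rnorm runif sd quantile optim uniroot integrate
#' @importFrom utils read.csv write.csv head combn
NULL

# Element tables. Covalent radii (Cordero-style, Angstrom) drive xyz bond
# perception; Sanderson electronegativities feed the GETAWAY weight scheme.
.elements <- data.frame(
  symbol  = c("H", "C", "N", "O", "S", "Cl", "Br"),
  cov_rad = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.02, 1.20),
  sanderson = c(2.592, 2.746, 3.194, 3.654, 2.957, 3.475, 3.219),
  valence = c(1L, 4L, 3L, 2L, 2L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Supported element symbols
#'
#' The fixed element table used for validation, bond perception and
#' descriptor weighting. Covers the chemistry of the studied sulfonamide
#' series (C, H, N, O, S plus the halogen substituents Cl and Br).
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() .elements$symbol

.element_prop <- function(symbols, prop) {
  idx <- match(symbols, .elements$symbol)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  .elements[[prop]][idx]
}

#' Construct a molecule
#'
#' A `molecule` is the substrate of every descriptor computation in the
#' package: an ordered list of atoms (element symbol plus Cartesian
#' coordinates in Angstrom), a bond list, and an isomer tag recording
#' whether the conformer represents the cis or trans configuration about
#' the central C=N hydrazone-type bond.
#'
#' @param id Character label for the species, e.g. `"1-trans"`.
#' @param elements Character vector of element symbols (one per atom).
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (bond order); one row per bond.
#' @param isomer One of `"cis"`, `"trans"`, `"unspecified"`.
#' @param validate Run invariant checks (connectivity, finite coordinates,
#'   minimum interatomic distance 0.5 Angstrom, supported elements)?
#'
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, elements, coords, bonds,
                     isomer = c("unspecified", "cis", "trans"),
                     validate = TRUE) {
  isomer <- match.arg(isomer)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  bonds <- as.data.frame(bonds)
  if (!all(c("i", "j", "order") %in% names(bonds))) {
    names(bonds)[seq_len(min(3L, ncol(bonds)))] <-
      c("i", "j", "order")[seq_len(min(3L, ncol(bonds)))]
  }
  if (is.null(bonds$order)) bonds$order <- 1L
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  mol <- structure(
    list(id = as.character(id), elements = as.character(elements),
         coords = coords, bonds = bonds[, c("i", "j", "order")],
         isomer = isomer),
    class = "molecule")
  if (validate) validate_molecule(mol)
  mol
}

#' Validate molecule invariants
#'
#' Checks that bond indices are in range, the bond graph is connected,
#' coordinates are finite, no two atoms sit closer than 0.5 Angstrom, and
#' all elements come from [supported_elements()].
#'
#' @param mol A [molecule()].
#' @return `mol`, invisibly; errors describe the first violated invariant.
#' @export
validate_molecule <- function(mol) {
  n <- n_atoms(mol)
  if (n < 1L) stop("molecule '", mol$id, "' has no atoms")
  if (length(mol$elements) != n) {
    stop("molecule '", mol$id, "': element/coordinate length mismatch")
  }
  .element_prop(mol$elements, "symbol")
  if (!all(is.finite(mol$coords))) {
    stop("molecule '", mol$id, "' has non-finite coordinates")
  }
  b <- mol$bonds
  if (nrow(b) > 0L &&
      (any(b$i < 1L | b$i > n) || any(b$j < 1L | b$j > n) || any(b$i == b$j))) {
    stop("molecule '", mol$id, "' has out-of-range or self bonds")
  }
  if (n > 1L) {
    d <- dist(mol$coords)
    if (min(d) < 0.5) {
      stop("molecule '", mol$id, "': atoms closer than 0.5 Angstrom (min ",
           format(min(d), digits = 4), ")")
    }
    comp <- .components(mol)
    if (max(comp) > 1L) {
      sizes <- table(comp)
      stop("molecule '", mol$id, "': bond graph is disconnected (",
           length(sizes), " components of sizes ",
           paste(sizes, collapse = ", "), ")")
    }
  }
  invisible(mol)
}

#' @rdname molecule
#' @export
n_atoms <- function(mol) nrow(mol$coords)

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, " [", x$isomer, "]: ", n_atoms(x), " atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)), collapse = ""),
      "), ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

.mol_graph <- function(mol) {
  igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                              directed = FALSE) +
    igraph::vertices(setdiff(seq_len(n_atoms(mol)),
                             unique(c(mol$bonds$i, mol$bonds$j))))
}

.components <- function(mol) {
  igraph::components(.mol_graph(mol))$membership
}

#' Topological distance matrix
#'
#' Shortest bond-path length (number of bonds) between every atom pair.
#' These integer "lags" index the GETAWAY autocorrelations and the CATS2D
#' pharmacophore-pair counts.
#'
#' @param mol A connected [molecule()].
#' @return Symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(mol) {
  comp <- .components(mol)
  if (max(comp) > 1L) {
    stop("bond graph is disconnected; components: ",
         paste(tapply(seq_along(comp), comp, paste, collapse = ","),
               collapse = " | "))
  }
  d <- igraph::distances(.mol_graph(mol))
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Geometric (Euclidean) distance matrix
#'
#' @param mol A [molecule()].
#' @return Symmetric numeric matrix of interatomic distances in Angstrom.
#' @export
geometric_distances <- function(mol) {
  as.matrix(dist(mol$coords))
}

#' Measure a dihedral angle
#'
#' Signed dihedral (torsion) angle defined by four atoms, in degrees,
#' using the standard IUPAC convention (looking along b-c, the angle from
#' the a-b projection to the c-d projection, positive clockwise).
#'
#' @param mol A [molecule()].
#' @param a,b,c,d 1-based atom indices of a bonded path a-b-c-d.
#' @return Angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(mol, a, b, c, d) {
  p <- mol$coords
  b1 <- p[b, ] - p[a, ]
  b2 <- p[c, ] - p[b, ]
  b3 <- p[d, ] - p[c, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Torsion specification
#'
#' Identifies the dihedral to drive when constructing the cis partner of a
#' trans conformer (or vice versa): four atom indices along a bonded path
#' a-b-c-d and the target angle. The central bond b-c must be acyclic so
#' that rotating the d-side of the molecule is well defined.
#'
#' @param a,b,c,d 1-based atom indices; a-b, b-c, c-d must be bonds.
#' @param target Target dihedral angle in degrees.
#' @return An object of class `torsion_spec`.
#' @export
torsion_spec <- function(a, b, c, d, target) {
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), target = as.numeric(target)),
            class = "torsion_spec")
}

.has_bond <- function(mol, i, j) {
  any((mol$bonds$i == i & mol$bonds$j == j) |
      (mol$bonds$i == j & mol$bonds$j == i))
}

#' Flip a torsion to a target angle
#'
#' Rotates the part of the molecule on the d-side of the central bond b-c
#' rigidly about the b-c axis until the dihedral (a,b,c,d) equals the
#' target angle. Bond lengths, angles within each rigid group, and the
#' full bond topology are preserved; only geometry across the driven bond
#' changes. Used to construct cis/trans isomer pairs that share topology,
#' the premise that lets 3D-sensitive descriptors separate what purely
#' topological descriptors cannot. The isomer tag is toggled
#' (cis to trans and vice versa) when the molecule carries one.
#'
#' @param mol A [molecule()].
#' @param spec A [torsion_spec()].
#' @return A new `molecule` with the driven dihedral at the target angle
#'   (within 1e-6 degrees).
#' @export
flip_torsion <- function(mol, spec) {
  for (pair in list(c(spec$a, spec$b), c(spec$b, spec$c), c(spec$c, spec$d))) {
    if (!.has_bond(mol, pair[1], pair[2])) {
      stop("torsion path is not bonded: no bond ", pair[1], "-", pair[2])
    }
  }
  # removing b-c must disconnect the graph, i.e. b-c is not in a ring
  keep <- !((mol$bonds$i == spec$b & mol$bonds$j == spec$c) |
            (mol$bonds$i == spec$c & mol$bonds$j == spec$b))
  cut <- mol
  cut$bonds <- mol$bonds[keep, , drop = FALSE]
  comp <- .components(cut)
  if (comp[spec$b] == comp[spec$c]) {
    stop("bond ", spec$b, "-", spec$c, " lies in a ring; torsion undefined")
  }
  moving <- which(comp == comp[spec$c])

  rotate_by <- function(theta) {
    axis <- mol$coords[spec$c, ] - mol$coords[spec$b, ]
    axis <- axis / sqrt(sum(axis^2))
    out <- mol
    rel <- sweep(mol$coords[moving, , drop = FALSE], 2, mol$coords[spec$b, ])
    out$coords[moving, ] <- sweep(rel %*% t(.rotation_matrix(axis, theta)),
                                  2, mol$coords[spec$b, ], `+`)
    out
  }
  cur <- measure_dihedral(mol, spec$a, spec$b, spec$c, spec$d)
  delta <- (spec$target - cur) * pi / 180
  out <- rotate_by(delta)
  got <- measure_dihedral(out, spec$a, spec$b, spec$c, spec$d)
  if (.angdiff(got, spec$target) > 1e-6) {
    out <- rotate_by(-delta)
    got <- measure_dihedral(out, spec$a, spec$b, spec$c, spec$d)
  }
  if (.angdiff(got, spec$target) > 1e-6) {
    stop("torsion drive failed: reached ", got, " deg, target ", spec$target)
  }
  out$isomer <- switch(mol$isomer, cis = "trans", trans = "cis",
                       "unspecified")
  out
}

.angdiff <- function(x, y) {
  d <- abs(x - y) %% 360
  min(d, 360 - d)
}

.rotation_matrix <- function(axis, theta) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  matrix(c(x * x * C + c_,     x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s,  y * y * C + c_,    y * z * C - x * s,
           z * x * C - y * s,  z * y * C + x * s, z * z * C + c_),
         3, 3, byrow = TRUE)
}
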
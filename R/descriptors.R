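#' Atomic weight scheme for GETAWAY descriptors
#'
#' GETAWAY autocorrelations weight each atom pair by an atomic property.
#' The scheme used throughout this package is Sanderson electronegativity
#' scaled so that carbon maps to 1 (the Dragon convention), shipped as a
#' static table for the supported elements.
#'
#' @param name Currently `"sanderson"` or `"unit"` (all weights 1, useful
#'   for unweighted checks).
#' @return An object of class `weight_scheme`: name, named weight vector,
#'   reference element.
#' @export
weight_scheme <- function(name = c("sanderson", "unit")) {
  name <- match.arg(name)
  w <- switch(name,
    sanderson = setNames(.elements$sanderson / .elements$sanderson[
      .elements$symbol == "C"], .elements$symbol),
    unit = setNames(rep(1, nrow(.elements)), .elements$symbol))
  structure(list(name = name, weights = w, reference = "C"),
            class = "weight_scheme")
}

.atom_weights <- function(mol, scheme) {
  w <- scheme$weights[mol$elements]
  if (anyNA(w)) {
    stop("no weight for element(s): ",
         paste(unique(mol$elements[is.na(w)]), collapse = ", "))
  }
  unname(w)
}

#' Center atomic coordinates
#'
#' Subtracts the geometric centroid so that column means are zero; the
#' centered coordinate matrix M is the input of the molecular influence
#' matrix H = M (M'M)^-1 M'.
#'
#' @param mol A [molecule()] or a numeric coordinate matrix (atoms x 3).
#' @return Centered coordinate matrix.
#' @export
center_coordinates <- function(mol) {
  m <- if (inherits(mol, "molecule")) mol$coords else as.matrix(mol)
  sweep(m, 2, colMeans(m))
}

#' Molecular influence matrix
#'
#' The hat matrix of the centered coordinates, H = M (M'M)^+ M' (computed
#' through the pseudo-inverse so planar and linear geometries are handled).
#' Its diagonal elements, the atomic leverages h_i in [0, 1], measure each
#' atom's contribution to the molecular shape; its trace equals the rank
#' of M (3 for a general 3D geometry, 2 planar, 1 linear). H is symmetric
#' and idempotent, and the leverages are invariant under rigid motion.
#'
#' @param coords Centered coordinate matrix (atoms x 3), e.g. from
#'   [center_coordinates()].
#' @return Square symmetric matrix H over atoms.
#' @export
influence_matrix <- function(coords) {
  m <- as.matrix(coords)
  if (nrow(m) < 1L) stop("no atoms")
  s <- svd(m)
  pos <- s$d > max(s$d[1], 0) * 1e-10
  if (!any(pos)) stop("all atoms coincident: influence matrix undefined")
  u <- s$u[, pos, drop = FALSE]
  h <- u %*% t(u)
  (h + t(h)) / 2
}

# Shared backbone of the H and R autocorrelations: pair index sets at a
# given topological lag plus the influence matrix of the molecule.
.getaway_context <- function(mol) {
  list(h = influence_matrix(center_coordinates(mol)),
       topo = topological_distances(mol),
       geo = geometric_distances(mol))
}

#' GETAWAY H autocorrelation
#'
#' `Hk(w) = sum over atom pairs i < j at topological distance k of
#' h_ij * w_i * w_j`, where h_ij are off-diagonal elements of the
#' molecular influence matrix and w the atomic weights. Negative h_ij are
#' truncated to zero by default (the reference convention), making the
#' descriptor non-negative. Hydrogens are included. Returns 0 when no
#' atom pair sits at the requested lag.
#'
#' @param mol A [molecule()].
#' @param scheme A [weight_scheme()]; default Sanderson electronegativity.
#' @param lag Topological distance k (non-negative integer).
#' @param truncate_negative Replace negative h_ij by 0 before summing?
#' @param ctx Precomputed [influence/topology context][getaway_h]; internal
#'   use for table building.
#' @return Dimensionless descriptor value.
#' @export
getaway_h <- function(mol, scheme = weight_scheme(), lag,
                      truncate_negative = TRUE, ctx = NULL) {
  stopifnot(lag >= 0)
  if (is.null(ctx)) ctx <- .getaway_context(mol)
  w <- .atom_weights(mol, scheme)
  hij <- ctx$h
  if (truncate_negative) hij <- pmax(hij, 0)
  sel <- ctx$topo == lag & upper.tri(ctx$topo)
  if (!any(sel)) return(0)
  ww <- outer(w, w)
  sum(hij[sel] * ww[sel])
}

#' GETAWAY R autocorrelation (sum and maximal variants)
#'
#' The R family combines leverages with geometry:
#' `Rk(w) = sum over pairs i < j at lag k of sqrt(h_i h_j) / r_ij * w_i *
#' w_j` with r_ij the Euclidean distance, and the maximal variant `Rk+`
#' takes the maximum of the same terms instead of the sum. Both are 0 when
#' no pair sits at the lag.
#'
#' @inheritParams getaway_h
#' @param variant `"sum"` for Rk or `"max"` for Rk+.
#' @return Dimensionless descriptor value.
#' @export
getaway_r <- function(mol, scheme = weight_scheme(), lag,
                      variant = c("sum", "max"), ctx = NULL) {
  variant <- match.arg(variant)
  stopifnot(lag >= 0)
  if (is.null(ctx)) ctx <- .getaway_context(mol)
  w <- .atom_weights(mol, scheme)
  lev <- diag(ctx$h)
  sel <- ctx$topo == lag & upper.tri(ctx$topo)
  if (!any(sel)) return(0)
  terms <- (outer(sqrt(pmax(lev, 0)), sqrt(pmax(lev, 0))) / ctx$geo *
            outer(w, w))[sel]
  if (variant == "sum") sum(terms) else max(terms)
}

#' @rdname getaway_r
#' @export
getaway_r_max <- function(mol, scheme = weight_scheme(), lag, ctx = NULL) {
  getaway_r(mol, scheme, lag, variant = "max", ctx = ctx)
}

# Potential pharmacophore point assignment on the heavy-atom graph.
# Donor: N or O bearing at least one hydrogen. Acceptor: N or O (lone
# pair assumed for the neutral chemistry covered here). Lipophilic: C, S,
# Cl or Br whose bonded neighbours are only C, H, S or halogens.
.ppp_types <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  el <- mol$elements
  lip_nb <- c("C", "H", "S", "Cl", "Br")
  types <- lapply(seq_len(n), function(i) {
    if (el[i] == "H") return(character())
    nb <- el[adj[[i]]]
    out <- character()
    if (el[i] %in% c("N", "O")) {
      out <- c(out, "A")
      if (any(nb == "H")) out <- c(out, "D")
    }
    if (el[i] %in% c("C", "S", "Cl", "Br") && all(nb %in% lip_nb)) {
      out <- c(out, "L")
    }
    out
  })
  types
}

.cats_pairs <- c("DD", "DA", "DL", "AA", "AL", "LL")

#' CATS2D pharmacophore-pair counts
#'
#' Counts of potential-pharmacophore-point (PPP) pairs - donor (D),
#' acceptor (A), lipophilic (L) - separated by a given number of bonds on
#' the heavy-atom graph, for lags 0 through `max_lag`. Raw counts are
#' reported (no scaling). At lag 0 an atom carrying both types of a
#' hetero pair (or the type of a homo pair) counts once. Being purely
#' topological, the full CATS2D vector is identical for a pair of
#' torsion-flipped cis/trans isomers.
#'
#' @param mol A [molecule()].
#' @param max_lag Largest topological distance tabulated (default 9).
#' @return Named integer vector, names like `CATS2D_07_DL`.
#' @export
cats2d <- function(mol, max_lag = 9L) {
  types <- .ppp_types(mol)
  heavy <- which(mol$elements != "H")
  topo <- topological_distances(mol)
  out <- integer((max_lag + 1L) * length(.cats_pairs))
  names(out) <- as.vector(t(outer(0:max_lag, .cats_pairs,
    function(l, p) sprintf("CATS2D_%02d_%s", l, p))))
  has <- lapply(c(D = "D", A = "A", L = "L"), function(t1)
    vapply(types, function(tt) t1 %in% tt, TRUE))
  for (pair in .cats_pairs) {
    t1 <- substr(pair, 1, 1); t2 <- substr(pair, 2, 2)
    # lag 0: single atoms carrying both roles of the pair
    out[sprintf("CATS2D_00_%s", pair)] <-
      sum(has[[t1]][heavy] & has[[t2]][heavy])
    # lag > 0: each unordered heavy pair {i, j} counts once when the two
    # roles can be assigned to it either way round
    for (a in seq_along(heavy)) {
      i <- heavy[a]
      for (b in seq_len(a - 1L)) {
        j <- heavy[b]
        lag <- topo[i, j]
        if (lag >= 1L && lag <= max_lag &&
            ((has[[t1]][i] && has[[t2]][j]) ||
             (has[[t2]][i] && has[[t1]][j]))) {
          nm <- sprintf("CATS2D_%02d_%s", lag, pair)
          out[nm] <- out[nm] + 1L
        }
      }
    }
  }
  out
}

#' Accessor for a single CATS2D descriptor
#'
#' @param mol A [molecule()].
#' @param lag Topological lag.
#' @param pair Pharmacophore pair type, e.g. `"DL"`.
#' @return Integer count, e.g. `cats2d_at(mol, 7, "DL")` is the
#'   donor-lipophilic count at lag 7 (Dragon name `CATS2D_07_DL`).
#' @export
cats2d_at <- function(mol, lag, pair) {
  unname(cats2d(mol, max_lag = max(9L, lag))[
    sprintf("CATS2D_%02d_%s", lag, pair)])
}

#' Sum of geometric distances between two element types
#'
#' The 3D atom-pair descriptor `G(A..B)`: the sum of Euclidean distances
#' over all unordered (A-atom, B-atom) pairs, in Angstrom. 0 when either
#' element is absent. Rotation/translation invariant but sensitive to
#' conformation, which is what makes it able to separate cis from trans.
#'
#' @param mol A [molecule()].
#' @param elemA,elemB Element symbols, e.g. `"S"` and `"Cl"`.
#' @return Distance sum in Angstrom.
#' @export
geom_pair_sum <- function(mol, elemA, elemB) {
  ia <- which(mol$elements == elemA)
  ib <- which(mol$elements == elemB)
  if (!length(ia) || !length(ib)) return(0)
  geo <- geometric_distances(mol)
  if (elemA == elemB) {
    if (length(ia) < 2L) return(0)
    sum(geo[ia, ia][upper.tri(geo[ia, ia])])
  } else {
    sum(geo[ia, ib, drop = FALSE])
  }
}

#' Compute the descriptor table for a set of species
#'
#' One row per species (compound id + isomer tag), columns for the GETAWAY
#' H and R+ autocorrelations over the configured lags (Sanderson
#' electronegativity weighting; Dragon-style names `H1e..H8e`,
#' `R1e+..R8e+`), the full CATS2D block, and `G(A..B)` geometric pair
#' sums over the supported element pairs. Deterministic: the same input
#' yields a bit-identical table.
#'
#' @param mols List of [molecule()] objects.
#' @param h_lags,r_lags Integer lags for the H and R+ families.
#' @param cats_max_lag Largest CATS2D lag.
#' @param g_elements Elements whose pairwise `G(..)` sums are tabulated.
#' @param scheme A [weight_scheme()].
#' @return Data frame with columns `species`, `compound`, `isomer`, then
#'   descriptors (names are Dragon-style and not syntactic R names; the
#'   table is built with `check.names = FALSE`).
#' @export
compute_descriptor_table <- function(mols, h_lags = 1:8, r_lags = 1:8,
                                     cats_max_lag = 9L,
                                     g_elements = c("N", "O", "S", "Cl", "Br"),
                                     scheme = weight_scheme()) {
  g_pairs <- t(combn(g_elements, 2L))
  rows <- lapply(mols, function(mol) {
    res <- tryCatch({
      ctx <- .getaway_context(mol)
      h <- vapply(h_lags, function(k)
        getaway_h(mol, scheme, k, ctx = ctx), 0)
      r <- vapply(r_lags, function(k)
        getaway_r_max(mol, scheme, k, ctx = ctx), 0)
      cats <- cats2d(mol, cats_max_lag)
      g <- apply(g_pairs, 1L, function(p) geom_pair_sum(mol, p[1], p[2]))
      c(setNames(h, sprintf("H%de", h_lags)),
        setNames(r, sprintf("R%de+", r_lags)),
        cats,
        setNames(g, sprintf("G(%s..%s)", g_pairs[, 1], g_pairs[, 2])))
    }, error = function(e) {
      stop("descriptor computation failed for molecule '", mol$id, "': ",
           conditionMessage(e))
    })
    res
  })
  vals <- do.call(rbind, rows)
  out <- data.frame(
    species = vapply(mols, function(m)
      if (m$isomer == "unspecified") m$id else paste0(m$id, "-", m$isomer),
      ""),
    compound = vapply(mols, function(m) m$id, ""),
    isomer = vapply(mols, function(m) m$isomer, ""),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Names of the descriptor columns of a descriptor table
#' @param table A table from [compute_descriptor_table()].
#' @return Character vector (everything after the id columns).
#' @export
descriptor_columns <- function(table) {
  setdiff(names(table), c("species", "compound", "isomer"))
}

#' Screen for isomer-differentiating descriptors
#'
#' Keeps a descriptor when its value differs between the cis and trans
#' member of at least one isomer pair by more than `tol`. CATS2D columns
#' are excluded up front: they are purely topological and cannot separate
#' torsion-flipped isomers, mirroring the preselection step in which only
#' blocks that respond to 3D geometry enter the regression pool.
#'
#' @param table Descriptor table from [compute_descriptor_table()].
#' @param pairs Data frame with columns `cis` and `trans` holding species
#'   labels present in `table$species`.
#' @param tol Absolute difference threshold (default 1e-6, the numeric
#'   noise floor of the descriptor computations).
#' @return Character vector of selected descriptor names.
#' @export
screen_isomer_differentiating <- function(table, pairs, tol = 1e-6) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no isomer pairs supplied for screening")
  }
  ic <- match(pairs$cis, table$species)
  it <- match(pairs$trans, table$species)
  if (anyNA(ic) || anyNA(it)) {
    stop("pair species not found in table: ",
         paste(c(pairs$cis[is.na(ic)], pairs$trans[is.na(it)]),
               collapse = ", "))
  }
  cols <- descriptor_columns(table)
  cols <- cols[!startsWith(cols, "CATS2D_")]
  keep <- vapply(cols, function(cn) {
    any(abs(table[[cn]][ic] - table[[cn]][it]) > tol)
  }, TRUE)
  cols[keep]
}

#' Write/read a descriptor table as CSV
#'
#' Header keeps the Dragon-style descriptor identifiers verbatim
#' (e.g. `R7e+`, `G(S..Cl)`).
#'
#' @param table Descriptor table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_descriptor_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
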
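# Synthetic-data generators. The studied structures themselves are not
# machine-readable, so every pipeline input is emulated with known ground
# truth: toy 3D molecules with sulfonamide-like decoration (S, Cl, Br, N,
# O on a carbon skeleton), torsion-flipped cis/trans partners sharing
# topology, descriptor-driven log kw values with Gaussian noise at the
# scale of the reference model's standard error (0.036 log units), and
# two-gradient retention tables from the LSS forward model. Geometry is
# idealized (fixed bond lengths, tetrahedral-ish angles), not
# force-field-optimized: descriptors need plausible, not physical,
# conformers.

#' Generate a toy 3D molecule
#'
#' Builds a connected heavy-atom skeleton - a six-membered carbon ring
#' plus a grown chain with single-atom substituents - with idealized bond
#' lengths (1.4-1.8 Angstrom) and angles, decorates it with the requested
#' elements (every requested element appears at least once), fills
#' valences with hydrogens, and sets the central chain torsion to 180
#' degrees (anti). The central acyclic chain bond is recorded in the
#' `"torsion"` attribute as a [torsion_spec()] so the cis partner can be
#' constructed by [flip_torsion()]. Deterministic per seed; the global
#' RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param n_heavy Number of heavy atoms (>= 10 for a ring plus a
#'   flippable chain).
#' @param elements Heavy-element menu; must contain `"C"`.
#' @return A validated [molecule()] tagged `trans`, with a `"torsion"`
#'   attribute.
#' @export
gen_toy_molecule <- function(seed, n_heavy = 16L,
                             elements = c("C", "N", "O", "S", "Cl", "Br")) {
  if (n_heavy < 12L) stop("n_heavy must be at least 12")
  if (!"C" %in% elements) stop("element menu must contain C")
  bad <- setdiff(elements, setdiff(supported_elements(), "H"))
  if (length(bad)) {
    stop("infeasible element menu; unsupported: ", paste(bad, collapse = ", "))
  }
  for (try in 0:29) {
    mol <- tryCatch(
      with_seed(seed * 1000L + try, .build_toy(n_heavy, elements, seed)),
      error = function(e) e)
    if (!inherits(mol, "error")) return(mol)
  }
  stop("toy-molecule generation failed for seed ", seed, ": ",
       conditionMessage(mol))
}

.build_toy <- function(n_heavy, elements, seed) {
  coords <- matrix(NA_real_, 0, 3)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  # ring: regular hexagon, side 1.4 A, in the xy plane
  ang <- seq(0, by = pi / 3, length.out = 6)
  coords <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = 1L)

  place_bonded <- function(anchor, blen, min_clash) {
    # direction away from the anchor's current neighbours, jittered
    nb <- c(bonds$j[bonds$i == anchor], bonds$i[bonds$j == anchor])
    push <- colSums(matrix(coords[anchor, ], length(nb), 3, byrow = TRUE) -
                    coords[nb, , drop = FALSE])
    for (k in 1:60) {
      dir <- push + rnorm(3, sd = 1.0 + 0.1 * k)
      dir <- dir / sqrt(sum(dir^2))
      pos <- coords[anchor, ] + blen * dir
      d <- sqrt(rowSums(sweep(coords, 2, pos)^2))
      d[anchor] <- Inf
      if (min(d) >= min_clash) return(pos)
    }
    stop("no clash-free placement found")
  }

  n_chain <- max(5L, n_heavy - 6L - 3L)
  n_sub <- n_heavy - 6L - n_chain
  chain <- integer(0)
  prev <- 1L
  for (s in seq_len(n_chain)) {
    pos <- place_bonded(prev, 1.5, 1.15)
    coords <- rbind(coords, pos)
    idx <- nrow(coords)
    bonds <- rbind(bonds, data.frame(i = prev, j = idx, order = 1L))
    chain <- c(chain, idx)
    prev <- idx
  }
  # single-atom substituents on interior chain atoms
  interior <- chain[seq_len(max(0L, length(chain) - 1L))]
  sub_idx <- integer(0)
  for (s in seq_len(n_sub)) {
    anchor <- interior[1L + (s - 1L) %% length(interior)]
    pos <- place_bonded(anchor, 1.7, 1.15)
    coords <- rbind(coords, pos)
    idx <- nrow(coords)
    bonds <- rbind(bonds, data.frame(i = anchor, j = idx, order = 1L))
    sub_idx <- c(sub_idx, idx)
  }

  # element assignment: ring stays carbon; substituents and chain atoms
  # carry the heteroatoms so every requested element appears at least
  # once. Monovalent elements (Cl, Br) need degree-1 slots, so elements
  # are placed in order of ascending valence over slots of ascending
  # degree (terminal substituents and the chain end first).
  el <- rep("C", nrow(coords))
  hetero <- setdiff(elements, "C")
  degree <- tabulate(c(bonds$i, bonds$j), nrow(coords))
  slots <- c(sub_idx, chain[length(chain)], rev(chain))
  slots <- slots[!duplicated(slots)]
  slots <- slots[order(degree[slots])]
  taken <- logical(nrow(coords))
  for (e in hetero[order(.element_prop(hetero, "valence"))]) {
    maxval <- .elements$valence[.elements$symbol == e]
    cand <- slots[!taken[slots] & degree[slots] <= maxval]
    if (!length(cand)) {
      stop("cannot place element ", e, " on a skeleton of ", n_heavy,
           " heavy atoms; enlarge n_heavy or shrink the menu")
    }
    el[cand[1]] <- e
    taken[cand[1]] <- TRUE
  }
  # sprinkle a few extra heteroatoms on remaining slots (keeps the
  # descriptor columns varied across compounds)
  for (cand in slots[!taken[slots]]) {
    if (runif(1) < 0.3 && length(hetero)) {
      e <- sample(hetero, 1L)
      if (degree[cand] <= .elements$valence[.elements$symbol == e]) {
        el[cand] <- e
      }
    }
  }

  # central torsion bond: mid-chain, flanked by bonded path a-b-c-d
  mid <- ceiling(length(chain) / 2)
  bthe <- chain[mid - 1L]; cthe <- chain[mid]
  athe <- if (mid >= 3L) chain[mid - 2L] else 1L
  dthe <- chain[mid + 1L]
  spec <- torsion_spec(athe, bthe, cthe, dthe, 180)

  # hydrogens fill remaining valence (1.0 A)
  val <- .element_prop(el, "valence")
  nh <- pmax(0L, val - degree)
  for (a in which(nh > 0L)) {
    for (h in seq_len(nh[a])) {
      pos <- place_bonded(a, 1.0, 0.85)
      coords <- rbind(coords, pos)
      idx <- nrow(coords)
      el <- c(el, "H")
      bonds <- rbind(bonds, data.frame(i = a, j = idx, order = 1L))
    }
  }

  mol <- molecule(as.character(seed), el, coords, bonds, isomer = "trans")
  mol <- flip_torsion(mol, spec)          # drive to exactly 180 (anti)
  mol$isomer <- "trans"
  # the cis partner must also satisfy the molecule invariants; reject
  # geometries whose syn form clashes so isomer pairs are always valid
  cis <- flip_torsion(mol, torsion_spec(athe, bthe, cthe, dthe, 0))
  validate_molecule(cis)
  attr(mol, "torsion") <- spec
  mol
}

#' Generate a cis/trans isomer series
#'
#' Emulates the study design of a two-gradient isomer-recognition
#' campaign: `n_compounds` trans conformers, each with a cis partner
#' obtained by flipping the central torsion from 180 to 0 degrees - except
#' one compound whose cis form is dropped (mirroring a species whose cis
#' peak is never observed), giving `2 * n_compounds - 1` species.
#'
#' @param seed Integer seed.
#' @param n_compounds Number of parent compounds (default 15).
#' @param drop_cis_for Compound id (integer) whose cis partner is
#'   omitted; `NULL` keeps all pairs. Default 4.
#' @param n_heavy_range Range of heavy-atom counts sampled per compound.
#' @param elements Heavy-element menu passed to [gen_toy_molecule()].
#' @return List of [molecule()]s (trans then cis per compound, in
#'   compound order), ids `"1".."n"`.
#' @export
gen_isomer_series <- function(seed, n_compounds = 15L, drop_cis_for = 4L,
                              n_heavy_range = c(14L, 20L),
                              elements = c("C", "N", "O", "S", "Cl", "Br")) {
  if (n_compounds < 1L) stop("n_compounds must be >= 1")
  if (!is.null(drop_cis_for) &&
      (drop_cis_for < 1L || drop_cis_for > n_compounds)) {
    stop("drop_cis_for out of range 1..", n_compounds)
  }
  sizes <- with_seed(seed,
    sample(seq(n_heavy_range[1], n_heavy_range[2]), n_compounds,
           replace = TRUE))
  out <- list()
  for (i in seq_len(n_compounds)) {
    tr <- gen_toy_molecule(seed + 101L * i, n_heavy = sizes[i],
                           elements = elements)
    tr$id <- as.character(i)
    out <- c(out, list(tr))
    if (is.null(drop_cis_for) || i != drop_cis_for) {
      spec <- attr(tr, "torsion")
      ci <- flip_torsion(tr, torsion_spec(spec$a, spec$b, spec$c, spec$d, 0))
      ci$id <- as.character(i)
      out <- c(out, list(ci))
    }
  }
  out
}

#' Simulate log kw from a descriptor table
#'
#' Generates the regression response `y = intercept + X beta + N(0,
#' sigma^2)` from named coefficients over descriptor columns, with the
#' noise scale defaulting to 0.036 log units (the standard error of
#' estimate of the reference retention model). Returns the ground truth
#' needed for recovery tests.
#'
#' @param table Descriptor table from [compute_descriptor_table()].
#' @param beta Named coefficient vector; names must be descriptor
#'   columns.
#' @param sigma Gaussian noise SD on log kw.
#' @param seed Integer seed.
#' @param intercept Model intercept (default 3.5, a typical log kw for
#'   the studied lipophilicity range).
#' @return List: `logkw` (named by species), `ground_truth` (list with
#'   `intercept`, `beta`, `sigma`, `seed`).
#' @export
simulate_logkw <- function(table, beta, sigma = 0.036, seed,
                           intercept = 3.5) {
  missing <- setdiff(names(beta), names(table))
  if (length(missing)) {
    stop("beta names not in descriptor table: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(table[, names(beta), drop = FALSE])
  y <- intercept + as.vector(X %*% beta) +
    with_seed(seed, rnorm(nrow(table), 0, sigma))
  list(logkw = setNames(y, table$species),
       ground_truth = list(intercept = intercept, beta = beta,
                           sigma = sigma, seed = seed))
}

#' Simulate a two-gradient retention table
#'
#' Forward-simulates retention times under the 30- and 60-min gradients
#' from per-species LSS parameters via [predict_gradient_tr()], adds
#' seeded Gaussian noise, and returns a raw retention table plus ground
#' truth. Species that would not elute within the program are flagged.
#'
#' @param params Named list of [lss_params()] (names become species
#'   labels), or a data frame with columns `species`, `logkw`, `s_value`.
#' @param g30,g60 [gradient_program()]s.
#' @param inst [instrument_params()].
#' @param tr_noise_sd Gaussian noise SD on each retention time (min),
#'   default 0.05.
#' @param seed Integer seed.
#' @return List: `table` (data frame `compound, isomer, tr_30, tr_60`;
#'   species labels of the form `id-isomer` are split, others land in
#'   `compound` with isomer `"unspecified"`), `ground_truth`.
#' @export
simulate_retention_table <- function(params, g30 = gradient_program(30),
                                     g60 = gradient_program(60), inst,
                                     tr_noise_sd = 0.05, seed) {
  if (is.data.frame(params)) {
    plist <- lapply(seq_len(nrow(params)), function(r)
      lss_params(params$logkw[r], params$s_value[r]))
    names(plist) <- params$species
    params <- plist
  }
  labels <- names(params)
  tr30 <- vapply(params, function(p)
    predict_gradient_tr(p, g30, inst), 0)
  tr60 <- vapply(params, function(p)
    predict_gradient_tr(p, g60, inst), 0)
  if (anyNA(c(tr30, tr60))) {
    stop("non-eluting species: ",
         paste(labels[is.na(tr30) | is.na(tr60)], collapse = ", "))
  }
  noise <- with_seed(seed, rnorm(2L * length(params), 0, tr_noise_sd))
  tr30 <- tr30 + noise[seq_along(params)]
  tr60 <- tr60 + noise[length(params) + seq_along(params)]
  has_tag <- grepl("-(cis|trans)$", labels)
  compound <- ifelse(has_tag, sub("-(cis|trans)$", "", labels), labels)
  isomer <- ifelse(has_tag, sub("^.*-", "", labels), "unspecified")
  list(table = data.frame(compound = compound, isomer = isomer,
                          tr_30 = unname(tr30), tr_60 = unname(tr60),
                          stringsAsFactors = FALSE),
       ground_truth = list(
         params = lapply(params, unclass),
         inst = unclass(inst), tr_noise_sd = tr_noise_sd, seed = seed))
}

#' Write a ground-truth sidecar
#'
#' Serializes the ground truth of a simulated dataset as JSON next to the
#' dataset so expectations can always be recomputed.
#'
#' @param ground_truth Ground-truth list from a simulator.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  # named vectors become JSON objects, so names survive even at length 1
  if (!is.null(ground_truth$beta) && !is.list(ground_truth$beta)) {
    ground_truth$beta <- as.list(ground_truth$beta)
  }
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
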
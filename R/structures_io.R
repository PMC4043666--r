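#' Read a molecular structure file
#'
#' Reads an MDL MOL/SDF (V2000) record or an XYZ file into a [molecule()].
#' SDF/MOL parsing is delegated to \pkg{ChemmineR}; atom indices are
#' 1-based in the file and kept 1-based internally. For XYZ input, which
#' carries no bond block, bonds are perceived from interatomic distances
#' using covalent radii with a 0.4 Angstrom tolerance, or taken from an
#' optional sidecar CSV with columns `i,j,order`.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"` (from extension), `"sdf"`, `"mol"`,
#'   `"xyz"`.
#' @param bonds_csv Optional path to a bond-list CSV for XYZ input.
#' @param id Species label; defaults to the file name (SDF title line is
#'   not relied on, many generators leave it blank).
#' @param isomer Isomer tag to attach (`"cis"`, `"trans"`,
#'   `"unspecified"`).
#' @return A validated [molecule()]. A 2D-only SDF (all z coordinates
#'   zero) triggers a warning, not an error.
#' @export
read_structure <- function(path, format = c("auto", "sdf", "mol", "xyz"),
                           bonds_csv = NULL, id = NULL,
                           isomer = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "mol", xyz = "xyz",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (format %in% c("sdf", "mol")) {
    mol <- .read_sdf_one(path, id, isomer)
  } else {
    mol <- .read_xyz(path, bonds_csv, id, isomer)
  }
  validate_molecule(mol)
  if (n_atoms(mol) > 2L && all(abs(mol$coords[, "z"]) < 1e-8)) {
    warning("structure '", id, "' appears to be 2D (all z = 0)")
  }
  mol
}

.read_sdf_one <- function(path, id, isomer) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("malformed SDF/MOL file '", path, "': ",
                             conditionMessage(e)))
  if (length(sdfset) < 1L) stop("no molecule record in '", path, "'")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  molecule(id, elements, coords, bonds, isomer, validate = FALSE)
}

.read_xyz <- function(path, bonds_csv, id, isomer) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ '", path, "': line 1 is not an atom count")
  if (length(lines) < n + 2L) {
    stop("malformed XYZ '", path, "': expected ", n, " atom lines")
  }
  toks <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad)) {
    stop("malformed XYZ '", path, "': atom line ", bad[1] + 2L,
         " has fewer than 4 fields")
  }
  elements <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(tk)
    suppressWarnings(as.numeric(tk[2:4])), numeric(3)))
  if (anyNA(coords)) stop("malformed XYZ '", path, "': non-numeric coordinate")
  if (!is.null(bonds_csv)) {
    bonds <- read.csv(bonds_csv)
  } else {
    bonds <- infer_bonds(elements, coords)
  }
  molecule(id, elements, coords, bonds, isomer, validate = FALSE)
}

#' Perceive bonds from geometry
#'
#' Two atoms are bonded when their distance does not exceed the sum of
#' their covalent radii plus a 0.4 Angstrom tolerance. Contacts falling
#' within 0.1 Angstrom below the cutoff are reported via a message
#' (ambiguous borderline contacts are bonded, but not silently).
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix of coordinates (atoms x 3, Angstrom).
#' @param tol Distance tolerance added to the radii sum (Angstrom).
#' @return Data frame with columns `i`, `j`, `order` (all order 1).
#' @export
infer_bonds <- function(elements, coords, tol = 0.4) {
  rad <- .element_prop(elements, "cov_rad")
  d <- as.matrix(dist(coords))
  cutoff <- outer(rad, rad, `+`) + tol
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit)) {
    margin <- cutoff[hit] - d[hit]
    borderline <- margin < 0.1
    if (any(borderline)) {
      message(sum(borderline), " borderline contact(s) within 0.1 Angstrom ",
              "of the bond cutoff were treated as bonds")
    }
  }
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
             order = rep(1L, nrow(hit)))
}

#' Write a molecular structure file
#'
#' Writes SDF (V2000, via \pkg{ChemmineR}) or XYZ. Coordinates are written
#' with 4 decimal places in SDF (the format's field width), so round trips
#' are lossless to 1e-4 Angstrom.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param format `"sdf"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = c("sdf", "xyz")) {
  format <- match.arg(format)
  if (format == "xyz") {
    lines <- c(as.character(n_atoms(mol)), mol$id,
               sprintf("%-2s %12.6f %12.6f %12.6f", mol$elements,
                       mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
    writeLines(lines, path)
  } else {
    writeLines(.as_molblock(mol), path)
  }
  invisible(path)
}

# V2000 writer: ChemmineR's write.SDF pads atom blocks through its own SDF
# class; emitting the fixed-width block directly keeps full control of the
# coordinate precision and the counts line.
.as_molblock <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  header <- c(mol$id, "  qsrriso", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$coords[, 1], mol$coords[, 2], mol$coords[, 3],
                   mol$elements)
  bonds <- if (nb) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j,
            mol$bonds$order)
  } else character()
  c(header, atoms, bonds, "M  END", "$$$$")
}

#' Write a distance matrix as CSV
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param type `"geometric"` (Angstrom) or `"topological"` (bond counts).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(mol, path,
                                  type = c("geometric", "topological")) {
  type <- match.arg(type)
  m <- switch(type, geometric = geometric_distances(mol),
              topological = topological_distances(mol))
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}
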
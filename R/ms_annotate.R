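# Accurate-mass shift reasoning for metabolite assignment. In the studied
# series the biotransformations observed by LC-MS are hydroxylation (+O),
# reductive debromination (-Br +H) and their combination; because every
# feature is measured as the same [M+H]+ adduct, the adduct mass cancels
# in pairwise mass differences and the assignment reduces to matching an
# observed delta-m against a small catalog of exact monoisotopic shifts.

# Monoisotopic masses of the most abundant isotope (Da), static table.
.isotope_masses <- c(
  H  = 1.00783,
  C  = 12.00000,
  N  = 14.00307,
  O  = 15.99491,
  S  = 31.97207,
  Cl = 34.96885,
  Br = 78.91834
)

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses over an elemental formula,
#' additive over formula concatenation. Elements may carry negative
#' counts, which is how transformation deltas such as `-Br +H` are
#' expressed.
#'
#' @param formula Either a named numeric vector of element counts, e.g.
#'   `c(H = 2, O = 1)`, or a formula string such as `"H2O"` or `"C6H5Br"`
#'   (no parentheses or charges).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  unknown <- setdiff(names(formula), names(.isotope_masses))
  if (length(unknown)) {
    stop("element(s) not in the isotope table: ",
         paste(unknown, collapse = ", "))
  }
  sum(.isotope_masses[names(formula)] * as.numeric(formula))
}

#' @rdname monoisotopic_mass
#' @export
parse_formula <- function(formula) {
  s <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' An accurate-mass feature
#'
#' @param label Feature name, e.g. `"M2"`.
#' @param mz m/z of the `[M+H]+` ion in Da.
#' @return Object of class `mass_feature`.
#' @export
mass_feature <- function(label, mz) {
  stopifnot(is.finite(mz), mz > 0)
  structure(list(label = as.character(label), mz = as.numeric(mz)),
            class = "mass_feature")
}

#' Catalog of biotransformation mass shifts
#'
#' Ships the transformations relevant to the studied series:
#' hydroxylation (+O), reductive debromination (-Br +H), and the two
#' combined. Each entry stores its elemental delta and the exact
#' monoisotopic shift, which is validated against [monoisotopic_mass()]
#' to 1e-4 Da on construction.
#'
#' @param extra Optional list of additional entries, each a list with
#'   `name` and `delta` (named numeric vector of signed element counts).
#' @return Data frame of class `transform_catalog` with columns `name`,
#'   `delta` (list column) and `shift` (Da).
#' @export
transform_catalog <- function(extra = NULL) {
  entries <- list(
    list(name = "hydroxylation",
         delta = c(O = 1)),
    list(name = "reductive debromination",
         delta = c(Br = -1, H = 1)),
    list(name = "hydroxylation + debromination",
         delta = c(O = 1, Br = -1, H = 1)))
  entries <- c(entries, extra)
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate transformation names")
  shifts <- vapply(entries, function(e) monoisotopic_mass(e$delta), 0)
  out <- data.frame(name = nms, shift = shifts, stringsAsFactors = FALSE)
  out$delta <- lapply(entries, `[[`, "delta")
  structure(out, class = c("transform_catalog", "data.frame"))
}

#' Annotate a candidate feature against a parent
#'
#' Computes the observed mass difference `candidate - parent` and returns
#' the catalog transformation minimizing `|observed - catalog shift|`,
#' considering each entry in both directions (a negative observed delta
#' matches the reverse of a gain transformation and is reported with
#' direction `"reverse"`). No match within `tol` returns `NULL`.
#'
#' @param parent,candidate [mass_feature()]s of the same adduct type.
#' @param catalog A [transform_catalog()].
#' @param tol Match tolerance in Da (default 0.05, a typical accurate-mass
#'   TOF tolerance).
#' @return List with `name`, `direction` (`"forward"`/`"reverse"`),
#'   `observed` (Da), `expected` (Da, signed as matched), `error` (Da);
#'   or `NULL` when nothing matches.
#' @export
annotate_pair <- function(parent, candidate, catalog = transform_catalog(),
                          tol = 0.05) {
  stopifnot(tol > 0)
  obs <- candidate$mz - parent$mz
  expected <- c(catalog$shift, -catalog$shift)
  err <- abs(obs - expected)
  i <- which.min(err)
  if (err[i] > tol) return(NULL)
  k <- ((i - 1L) %% nrow(catalog)) + 1L
  list(name = catalog$name[k],
       direction = if (i <= nrow(catalog)) "forward" else "reverse",
       observed = obs,
       expected = expected[i],
       error = err[i])
}

#' Annotate a run of features against one parent
#'
#' @param parent A [mass_feature()].
#' @param features List of [mass_feature()]s, order preserved in the
#'   report.
#' @param catalog A [transform_catalog()].
#' @param tol Tolerance in Da.
#' @return Data frame with one row per feature: `label`, `mz`,
#'   `observed_shift`, `transformation` (`NA` for unannotated features),
#'   `direction`, `error`.
#' @export
annotate_run <- function(parent, features, catalog = transform_catalog(),
                         tol = 0.05) {
  if (!length(features)) {
    return(data.frame(label = character(), mz = numeric(),
                      observed_shift = numeric(),
                      transformation = character(), direction = character(),
                      error = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(features, function(f) {
    ann <- annotate_pair(parent, f, catalog, tol)
    data.frame(label = f$label, mz = f$mz,
               observed_shift = f$mz - parent$mz,
               transformation = if (is.null(ann)) NA_character_ else ann$name,
               direction = if (is.null(ann)) NA_character_ else ann$direction,
               error = if (is.null(ann)) NA_real_ else ann$error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(label = character(), mz = numeric(),
                      observed_shift = numeric(),
                      transformation = character(), direction = character(),
                      error = numeric(), stringsAsFactors = FALSE)
  }
  out
}
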
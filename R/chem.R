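# Exact mass arithmetic: isotope tables, elemental compositions, residue and
# peptide masses, and the PTM registry used throughout the pipeline.

# IUPAC monoisotopic isotope masses (Da); C-12 is exact by definition.
.ISO_MONO <- c(
  C = 12,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  P = 30.973761998,
  S = 31.972071174
)

# Standard atomic weights (abundance-averaged), for intact-protein work.
.ISO_AVG <- c(
  C = 12.0107,
  H = 1.00794,
  N = 14.0067,
  O = 15.9994,
  P = 30.973762,
  S = 32.065
)

.ELEMENTS <- names(.ISO_MONO)

#' Mass of a proton (Da), used for m/z arithmetic
#' @export
PROTON_MASS <- 1.007276467

#' Construct an elemental composition
#'
#' An `element_counts` object holds non-negative integer atom counts over the
#' CHNOPS element set. Compositions support `+` and feed
#' [composition_mass()] and [rdbe()].
#'
#' @param c,h,n,o,p,s Non-negative integer atom counts.
#' @return An object of class `element_counts` (named integer vector).
#' @examples
#' methylpyrroline <- element_counts(c = 6, h = 7, n = 1, o = 1)
#' composition_mass(methylpyrroline)  # 109.052764
#' @export
element_counts <- function(c = 0, h = 0, n = 0, o = 0, p = 0, s = 0) {
  x <- c(C = c, H = h, N = n, O = o, P = p, S = s)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers")
  structure(as.integer(round(x)), names = .ELEMENTS, class = "element_counts")
}

#' @export
`+.element_counts` <- function(e1, e2) {
  structure(as.integer(unclass(e1) + unclass(e2)),
            names = .ELEMENTS, class = "element_counts")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<composition>", formula_string(x), "\n")
  invisible(x)
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas over CHNOPS such as `"C2H2O"` or `"HPO3"`; an element
#' without a trailing number counts once.
#'
#' @param x Formula string.
#' @return An [element_counts()] object.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "") return(element_counts())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: ", x)
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    k <- sub("^[A-Za-z]+", "", tok)
    k <- if (k == "") 1L else as.integer(k)
    if (!el %in% .ELEMENTS) stop("unsupported element '", el, "' in formula ", x)
    counts[el] <- counts[el] + k
  }
  do.call(element_counts, as.list(stats::setNames(counts, tolower(.ELEMENTS))))
}

#' Write a composition as a Hill-notation formula string
#' @param comp An [element_counts()] object.
#' @return A string, e.g. `"C6H7NO"`; the empty composition gives `""`.
#' @export
formula_string <- function(comp) {
  x <- unclass(comp)
  parts <- character(0)
  for (el in c("C", "H", "N", "O", "P", "S")) {
    k <- x[[el]]
    if (k > 0) parts <- c(parts, paste0(el, if (k > 1) k else ""))
  }
  paste0(parts, collapse = "")
}

#' Monoisotopic or average mass of an elemental composition
#'
#' The mass is the exact linear combination of atom counts with isotope
#' (monoisotopic) or standard atomic (average) masses, and is additive over
#' composition addition.
#'
#' @param comp An [element_counts()] object (or a formula string).
#' @param kind `"mono"` (default) or `"average"`.
#' @return Mass in Da; the empty composition has mass 0.
#' @examples
#' composition_mass(parse_formula("C6H7NO"))            # 109.052764
#' composition_mass(parse_formula("C2H2O"))             # acetyl, 42.010565
#' @export
composition_mass <- function(comp, kind = c("mono", "average")) {
  kind <- match.arg(kind)
  if (is.character(comp)) comp <- parse_formula(comp)
  tab <- if (kind == "mono") .ISO_MONO else .ISO_AVG
  sum(unclass(comp) * tab)
}

#' Ring-and-double-bond equivalents of a composition
#'
#' RDBE = C - H/2 + N/2 + 1. Phosphorus and sulfur are ignored (documented
#' convention: P is not given an N-like trivalent contribution). Half-integer
#' results flag odd-electron (radical) compositions.
#'
#' @param comp An [element_counts()] object.
#' @return A (possibly half-integer) numeric value; 1 for the empty composition.
#' @export
rdbe <- function(comp) {
  x <- unclass(comp)
  x[["C"]] - x[["H"]] / 2 + x[["N"]] / 2 + 1
}

# Residue elemental compositions (residue = amino acid minus water).
.RESIDUE_FORMULAS <- list(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",   V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS",  L = "C6H11NO",  I = "C6H11NO",  N = "C4H6N2O2",
  D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",
  H = "C6H7N3O", F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.residue_table <- local({
  res <- names(.RESIDUE_FORMULAS)
  comp <- lapply(.RESIDUE_FORMULAS, parse_formula)
  data.frame(
    residue = res,
    mono = vapply(comp, composition_mass, numeric(1), kind = "mono"),
    average = vapply(comp, composition_mass, numeric(1), kind = "average"),
    row.names = res, stringsAsFactors = FALSE
  )
})

.WATER_MONO <- composition_mass(element_counts(h = 2, o = 1))
.WATER_AVG <- composition_mass(element_counts(h = 2, o = 1), "average")
.ACETYL_MONO <- composition_mass(parse_formula("C2H2O"))
.ACETYL_AVG <- composition_mass(parse_formula("C2H2O"), "average")

#' Residue mass table for the 20 canonical amino acids
#'
#' @return A data.frame with columns `residue`, `mono` and `average`
#'   (Da, residue masses, i.e. amino acid minus water).
#' @export
residue_masses <- function() .residue_table

.residue_vector <- function(kind = "mono") {
  stats::setNames(.residue_table[[kind]], .residue_table$residue)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("empty peptide")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, .residue_table$residue)
  if (length(bad))
    stop("unknown residue '", bad[1], "' in sequence")
  aa
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Mass = sum of residue monoisotopic masses + water (18.010565 Da) + the sum
#' of modification deltas, + 42.010565 Da if the N-terminus is acetylated.
#'
#' @param sequence Peptide sequence (canonical one-letter codes).
#' @param placements Optional data.frame with columns `position` (1-based,
#'   within the peptide) and either `mass` (delta in Da) or `name` resolved
#'   against `registry`.
#' @param registry A [mod_registry()] used to resolve placement names.
#' @param nterm_acetyl Logical; add an N-terminal acetyl group.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")    # 75.03203
#' @export
peptide_mass <- function(sequence, placements = NULL, registry = NULL,
                         nterm_acetyl = FALSE) {
  aa <- .check_sequence(sequence)
  mv <- .residue_vector("mono")
  mass <- sum(mv[aa]) + .WATER_MONO + if (nterm_acetyl) .ACETYL_MONO else 0
  if (!is.null(placements) && nrow(placements)) {
    if (any(placements$position < 1L | placements$position > length(aa)))
      stop("modification position outside peptide")
    mass <- mass + sum(placement_masses(placements, registry))
  }
  mass
}

# Resolve placement deltas: prefer an explicit mass column, else registry names.
placement_masses <- function(placements, registry = NULL) {
  if (!is.null(placements$mass) && !anyNA(placements$mass))
    return(as.numeric(placements$mass))
  if (is.null(registry))
    stop("placements without a 'mass' column need a registry")
  vapply(placements$name, function(nm) registry_get(registry, nm)$mono,
         numeric(1))
}

#' Define a post-translational modification
#'
#' A modification carries either an elemental composition (from which both
#' monoisotopic and average deltas are derived) or, for unknown mass shifts, a
#' bare monoisotopic mass. All downstream code handles both representations.
#'
#' @param name Unique name within a registry.
#' @param formula Hill-notation formula string, or `NULL` for bare-mass entries.
#' @param mass Bare monoisotopic delta (Da); required when `formula` is `NULL`.
#' @param targets Character vector of residues and/or terminus flags
#'   (`"protein-nterm"`, `"peptide-nterm"`, `"peptide-cterm"`).
#' @param class Modification class label (e.g. `"phospho"`, `"acetyl"`,
#'   `"aa-adduct"`, `"unknown"`).
#' @return An object of class `modification`.
#' @export
modification <- function(name, formula = NULL, mass = NULL, targets, class) {
  stopifnot(is.character(name), nchar(name) > 0)
  comp <- if (!is.null(formula) && nzchar(formula)) parse_formula(formula) else NULL
  mono <- if (!is.null(comp)) composition_mass(comp) else as.numeric(mass)
  avg <- if (!is.null(comp)) composition_mass(comp, "average") else NA_real_
  if (is.null(mono) || is.na(mono))
    stop("modification '", name, "' needs a formula or a mass")
  if (mono <= -200 || mono >= 1000)
    stop("modification delta out of range (-200, 1000) Da: ", name)
  structure(
    list(name = name, formula = comp, mono = mono, average = avg,
         targets = as.character(targets), class = class),
    class = "modification"
  )
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s [%s] %+0.6f Da on %s\n", x$name, x$class,
              x$mono, paste(x$targets, collapse = ",")))
  invisible(x)
}

#' Build a modification registry
#'
#' @param mods A list of [modification()] objects with unique names.
#' @return An object of class `mod_registry`.
#' @export
mod_registry <- function(mods) {
  nms <- vapply(mods, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate modification name: ",
                               nms[duplicated(nms)][1])
  structure(list(mods = stats::setNames(mods, nms)), class = "mod_registry")
}

#' Look up a modification by name
#' @param registry A [mod_registry()].
#' @param name Modification name.
#' @export
registry_get <- function(registry, name) {
  m <- registry$mods[[name]]
  if (is.null(m)) stop("no modification named '", name, "' in registry")
  m
}

#' Registry as a data.frame
#' @param registry A [mod_registry()].
#' @return data.frame with columns name, formula, mono, average, targets, class.
#' @export
registry_table <- function(registry) {
  mods <- registry$mods
  data.frame(
    name = vapply(mods, `[[`, character(1), "name"),
    formula = vapply(mods, function(m)
      if (is.null(m$formula)) "" else formula_string(m$formula), character(1)),
    mono = vapply(mods, `[[`, numeric(1), "mono"),
    average = vapply(mods, `[[`, numeric(1), "average"),
    targets = vapply(mods, function(m) paste(m$targets, collapse = ","),
                     character(1)),
    class = vapply(mods, `[[`, character(1), "class"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.mod_registry <- function(x, ...) {
  cat("<mod_registry> with", length(x$mods), "modifications\n")
  print(registry_table(x)[, c("name", "formula", "mono", "targets", "class")],
        digits = 10)
  invisible(x)
}

#' The default PTM registry
#'
#' The modification set observed on Arabidopsis linker histones:
#' phosphorylation, acetylation, mono-/di-methylation, formylation,
#' crotonylation, propionylation, the putative methylpyrroline and
#' phosphoglycerol adducts, isopeptide amino-acid adducts on lysine (K, KV,
#' KH, modelled as sums of residue masses without terminal water, i.e. an
#' isopeptide branch), an arginine-residue adduct on glutamate, and the
#' unidentified 84.020 Da lysine modification (bare mass, no composition).
#'
#' @return A [mod_registry()].
#' @examples
#' reg <- default_registry()
#' registry_get(reg, "dimethyl")$mono - registry_get(reg, "formyl")$mono # 0.036
#' @export
default_registry <- function() {
  mod_registry(list(
    modification("phospho", "HPO3", targets = c("S", "T", "Y"), class = "phospho"),
    modification("acetyl", "C2H2O", targets = c("K", "protein-nterm"),
                 class = "acetyl"),
    modification("methyl", "CH2", targets = c("K", "R", "N"), class = "methyl"),
    modification("dimethyl", "C2H4", targets = "K", class = "dimethyl"),
    modification("formyl", "CO", targets = "K", class = "formyl"),
    modification("crotonyl", "C4H4O", targets = "K", class = "crotonyl"),
    modification("propionyl", "C3H4O", targets = "K", class = "propionyl"),
    modification("methylpyrroline", "C6H7NO", targets = c("K", "T"),
                 class = "methylpyrroline"),
    modification("phosphoglycerol", "C3H7O5P", targets = c("S", "T"),
                 class = "phosphoglycerol"),
    modification("K-adduct", "C6H12N2O", targets = "K", class = "aa-adduct"),
    modification("KV-adduct", "C11H21N3O2", targets = "K", class = "aa-adduct"),
    modification("KH-adduct", "C12H19N5O2", targets = "K", class = "aa-adduct"),
    modification("R-adduct", "C6H12N4O", targets = "E", class = "aa-adduct"),
    modification("unknown-84.020", mass = 84.020, targets = "K",
                 class = "unknown")
  ))
}

#' Read / write a PTM registry as TSV
#'
#' Columns: `name`, `formula` (Hill notation; empty for bare-mass entries),
#' `mass` (used when `formula` is empty), `targets` (comma-separated),
#' `class`. Round-trips every delta to better than 1e-6 Da.
#'
#' @param path File path.
#' @param registry A [mod_registry()] (for writing).
#' @return `read_registry()` returns a [mod_registry()].
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(name = "character",
                                         formula = "character"))
  mods <- lapply(seq_len(nrow(df)), function(i) {
    modification(df$name[i],
                 formula = if (nzchar(df$formula[i])) df$formula[i] else NULL,
                 mass = if (!nzchar(df$formula[i])) df$mass[i] else NULL,
                 targets = strsplit(df$targets[i], ",", fixed = TRUE)[[1]],
                 class = df$class[i])
  })
  mod_registry(mods)
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  tab <- registry_table(registry)
  out <- data.frame(name = tab$name, formula = tab$formula,
                    mass = sprintf("%.7f", tab$mono),
                    targets = tab$targets, class = tab$class,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
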
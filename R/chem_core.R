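## Monoisotopic masses of the most abundant isotopes. All compounds in
## scope are CHO(N,S); extend via options(coumascreen.extra_elements = c(X = mass)).
.ISOTOPE_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

## Proton mass (H atom minus one electron): required for ppm-level
## [M+H]+ arithmetic even though 2-decimal display masks the difference.
.PROTON_MASS <- 1.0072765

.ELECTRON_MASS <- 0.000548579909

.ADDUCT_SHIFTS <- c(
  "[M+H]+"   = 1.0072765,
  "[M+Na]+"  = 22.98976928 - 0.000548579909,
  "[M+NH4]+" = 14.0030740052 + 4 * 1.0078250319 - 0.000548579909
)

element_masses <- function() {
  extra <- getOption("coumascreen.extra_elements", NULL)
  if (is.null(extra)) .ISOTOPE_MASS else c(.ISOTOPE_MASS, extra)
}

#' Parse a Hill-style molecular formula
#'
#' Converts a plain-text molecular formula such as `"C10H8O4"` into a
#' named integer vector of element counts (the elemental composition used
#' by all mass arithmetic in the package). Repeated element symbols are
#' summed, so `"CH3CH3"` parses to `c(C = 2, H = 6)`.
#'
#' @param formula Character scalar, e.g. `"C10H8O4"` or `"CO2"`. An
#'   omitted multiplier means 1.
#' @return Named integer vector of element counts, in Hill order
#'   (C first, then H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C10H8O4")   # scopoletin
#' parse_formula("CO2")
#' @seealso [monoisotopic_mass()], [formula_string()]
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("`formula` must be a single character string")
  formula <- gsub("[[:space:]]", "", formula)
  if (!nzchar(formula)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  syms <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- names(element_masses())
  bad <- setdiff(syms, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  comp <- tapply(counts, syms, sum)
  comp <- comp[comp > 0]
  if (!length(comp)) stop("formula has no atoms: ", formula)
  .hill_order(stats::setNames(as.integer(comp), names(comp)))
}

.hill_order <- function(comp) {
  nm <- names(comp)
  rest <- sort(setdiff(nm, c("C", "H")))
  ord <- c(intersect(c("C", "H"), nm), rest)
  comp[ord]
}

as_composition <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0)) stop("negative element count")
    return(.hill_order(x[x > 0]))
  }
  stop("expected a formula string or a named count vector")
}

#' Canonical Hill formula string for a composition
#'
#' @param comp Named count vector (or formula string, which is
#'   re-canonicalized).
#' @return Character scalar in Hill order; counts of 1 are implicit.
#' @examples
#' formula_string(c(O = 2, C = 1)) # "CO2"
#' @export
formula_string <- function(comp) {
  comp <- as_composition(comp)
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = "")
}

#' Add or subtract elemental compositions
#'
#' Subtraction errors if any resulting count would be negative (you
#' cannot lose a moiety the ion does not contain).
#'
#' @param a,b Compositions (named count vectors or formula strings).
#' @return Named count vector.
#' @export
composition_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  all_el <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .hill_order(out[out > 0])
}

#' @rdname composition_add
#' @export
composition_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  all_el <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("subtraction yields negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  .hill_order(out[out > 0])
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of count times most-abundant-isotope mass
#' (C = 12 exactly, H = 1.0078250319, O = 15.9949146221,
#' N = 14.0030740052, S = 31.97207069).
#'
#' @param comp Composition (named count vector) or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10H8O4") # 192.04226
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  if (!length(comp)) stop("empty composition")
  masses <- element_masses()
  missing <- setdiff(names(comp), names(masses))
  if (length(missing))
    stop("no isotope mass for element(s): ", paste(missing, collapse = ", "))
  sum(comp * masses[names(comp)])
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' For `[M+H]+` this is `mass + 1.0072765` (proton mass; the electron is
#' accounted for). Supported adducts: `[M+H]+`, `[M+Na]+`, `[M+NH4]+`.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param adduct Adduct label; default `"[M+H]+"` (the paper's
#'   positive-mode convention).
#' @return m/z at full precision; use [display_mz()] for the 2-decimal
#'   reporting convention.
#' @examples
#' adduct_mz(monoisotopic_mass("C10H8O4")) # 193.0495 -> displays 193.05
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+") {
  if (!is.numeric(mass) || any(mass < 0)) stop("`mass` must be non-negative")
  if (!adduct %in% names(.ADDUCT_SHIFTS))
    stop("unsupported adduct: ", adduct,
         " (supported: ", paste(names(.ADDUCT_SHIFTS), collapse = ", "), ")")
  mass + .ADDUCT_SHIFTS[[adduct]]
}

#' Round half-up (reporting convention)
#'
#' Base R `round()` rounds half to even; published m/z values use
#' conventional half-up rounding at 2 decimals.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @rdname round_half_up
#' @export
display_mz <- function(x, digits = 2) round_half_up(x, digits)

#' Mass tolerance specification
#'
#' A tolerance is relative (ppm), absolute (Da), or the wider of both at
#' any given m/z. The workflow defaults are 10 ppm at the precursor
#' level and wider-of(20 ppm, 0.01 Da) at the fragment level.
#'
#' @param ppm Relative tolerance in parts-per-million (or `NULL`).
#' @param dalton Absolute tolerance in Da (or `NULL`).
#' @param mode `"relative"`, `"absolute"` or `"wider"`; defaults to the
#'   mode implied by which bounds are given.
#' @return A `mass_tolerance` object.
#' @examples
#' mass_tolerance(ppm = 10)
#' fragment_tolerance() # wider-of(20 ppm, 0.01 Da)
#' @export
mass_tolerance <- function(ppm = NULL, dalton = NULL, mode = NULL) {
  if (is.null(ppm) && is.null(dalton))
    stop("at least one of `ppm`, `dalton` must be given")
  if (!is.null(ppm) && ppm <= 0) stop("`ppm` must be positive")
  if (!is.null(dalton) && dalton <= 0) stop("`dalton` must be positive")
  if (is.null(mode))
    mode <- if (!is.null(ppm) && !is.null(dalton)) "wider"
            else if (!is.null(ppm)) "relative" else "absolute"
  mode <- match.arg(mode, c("relative", "absolute", "wider"))
  if (mode == "relative" && is.null(ppm)) stop("relative mode needs `ppm`")
  if (mode == "absolute" && is.null(dalton)) stop("absolute mode needs `dalton`")
  if (mode == "wider" && (is.null(ppm) || is.null(dalton)))
    stop("wider mode needs both `ppm` and `dalton`")
  structure(list(ppm = ppm, dalton = dalton, mode = mode),
            class = "mass_tolerance")
}

#' @rdname mass_tolerance
#' @export
precursor_tolerance <- function(ppm = 10) mass_tolerance(ppm = ppm)

#' @rdname mass_tolerance
#' @export
fragment_tolerance <- function(ppm = 20, dalton = 0.01)
  mass_tolerance(ppm = ppm, dalton = dalton, mode = "wider")

#' Effective tolerance window (Da) at a given m/z
#'
#' @param tol A [mass_tolerance()].
#' @param mz m/z at which the relative component is evaluated.
#' @return Window half-width in Da (vectorized over `mz`).
#' @export
tolerance_window <- function(tol, mz) {
  stopifnot(inherits(tol, "mass_tolerance"))
  rel <- if (!is.null(tol$ppm)) tol$ppm * 1e-6 * mz else 0
  abs_ <- if (!is.null(tol$dalton)) rep(tol$dalton, length(mz)) else 0
  switch(tol$mode,
         relative = rel,
         absolute = abs_,
         wider = pmax(rel, abs_))
}

#' Test whether two m/z values agree within tolerance
#'
#' Symmetric in its two m/z arguments: the relative window is evaluated
#' at the mean of the pair.
#'
#' @param observed,theoretical m/z values (> 0); `theoretical` may be a
#'   vector.
#' @param tol A [mass_tolerance()].
#' @return Logical (vectorized over `theoretical`).
#' @examples
#' within_tolerance(193.0505, 193.0495, mass_tolerance(ppm = 10)) # TRUE
#' @export
within_tolerance <- function(observed, theoretical, tol) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("m/z values must be positive")
  abs(observed - theoretical) <=
    tolerance_window(tol, (observed + theoretical) / 2)
}

#' Signed relative difference in ppm
#'
#' @param observed,theoretical m/z values.
#' @export
ppm_difference <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
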
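#' Elemental formulas: parsing, arithmetic and molar mass
#'
#' An `elemental_formula` is the numeric substrate for every unit conversion
#' and balance check in the package: a named numeric vector of element counts
#' (fractional counts allowed -- pseudo-metabolite formulas are stoichiometry
#' weighted averages) plus a net charge in elementary charge units. A charge
#' of `NA` means "unknown", which is deliberately distinct from 0: combining
#' any species of unknown charge yields an unknown charge, never a silent 0.
#'
#' @name chem
NULL

# IUPAC standard atomic weights (2021 abridged), g/mol. Static on purpose:
# balance checks must not drift with an external package version. Pseudo
# element tokens occasionally found in GEM formulas ("R", "X") parse fine but
# have no mass; molar_mass() fails loudly only when a mass is actually needed.
.atomic_weights <- c(
  H = 1.008,    He = 4.0026,  Li = 6.94,    Be = 9.0122,  B = 10.81,
  C = 12.011,   N = 14.007,   O = 15.999,   F = 18.998,   Ne = 20.180,
  Na = 22.990,  Mg = 24.305,  Al = 26.982,  Si = 28.085,  P = 30.974,
  S = 32.06,    Cl = 35.45,   Ar = 39.95,   K = 39.098,   Ca = 40.078,
  V = 50.942,   Cr = 51.996,  Mn = 54.938,  Fe = 55.845,  Co = 58.933,
  Ni = 58.693,  Cu = 63.546,  Zn = 65.38,   As = 74.922,  Se = 78.971,
  Br = 79.904,  Mo = 95.95,   I = 126.90,   W = 183.84,   Cd = 112.41,
  Sn = 118.71,  Ba = 137.33,  Hg = 200.59,  Pb = 207.2
)

#' Atomic mass table
#'
#' @return Named numeric vector mapping element symbols to IUPAC standard
#'   atomic weights in g/mol.
#' @export
atomic_masses <- function() .atomic_weights

new_formula <- function(counts = numeric(0), charge = NA_real_) {
  counts <- counts[counts != 0]
  structure(list(counts = counts, charge = charge), class = "elemental_formula")
}

#' Parse a Hill-style elemental formula string
#'
#' Accepts element symbols (capital letter plus optional lowercase) each
#' followed by an optional integer or decimal count; a missing count means 1
#' and repeated symbols are summed. Symbols absent from [atomic_masses()]
#' (e.g. the pseudo-elements `R` or `X` used by some models) are accepted;
#' they only fail later if a molar mass is requested.
#'
#' @param formula_string Non-empty formula string, e.g. `"C6H12O6"` or
#'   `"C3.5H7O1.75"`.
#' @param charge Optional net charge to attach (default unknown, `NA`).
#' @return An `elemental_formula`.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O", charge = 0)
#' @export
parse_formula <- function(formula_string, charge = NA_real_) {
  if (!is.character(formula_string) || length(formula_string) != 1L ||
      is.na(formula_string) || !nzchar(formula_string)) {
    bof_error("bofkit_parse_error", "formula string must be a non-empty character scalar")
  }
  s <- formula_string
  tokens <- gregexpr("[A-Z][a-z]?([0-9]+(\\.[0-9]+)?)?", s)[[1]]
  starts <- as.integer(tokens)
  lens <- attr(tokens, "match.length")
  if (starts[1] == -1L || sum(lens) != nchar(s)) {
    # locate the first unmatched position for the error message
    covered <- rep(FALSE, nchar(s))
    if (starts[1] != -1L) {
      for (i in seq_along(starts)) covered[seq(starts[i], length.out = lens[i])] <- TRUE
    }
    pos <- which(!covered)[1]
    bad <- substr(s, pos, min(nchar(s), pos + 2L))
    bof_error("bofkit_parse_error", sprintf(
      "cannot parse formula '%s': unexpected token '%s' at position %d", s, bad, pos))
  }
  counts <- numeric(0)
  for (i in seq_along(starts)) {
    tok <- substr(s, starts[i], starts[i] + lens[i] - 1L)
    sym <- sub("[0-9.]*$", "", tok)
    num <- substr(tok, nchar(sym) + 1L, nchar(tok))
    n <- if (nzchar(num)) as.numeric(num) else 1
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  # Two-letter symbols must be known if their one-letter prefix would also be
  # invalid -- we accept unknown symbols (pseudo-elements) but still reject
  # plainly malformed ones like "Xq" where neither form is an element and the
  # token is not a conventional pseudo-element (single uppercase letter).
  unknown <- setdiff(names(counts), names(.atomic_weights))
  bad <- unknown[nchar(unknown) > 1L]
  if (length(bad)) {
    bof_error("bofkit_parse_error", sprintf(
      "cannot parse formula '%s': unknown element symbol(s) %s",
      s, paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  new_formula(counts, charge)
}

#' Serialize an elemental formula to Hill order
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically (plain
#' alphabetical when no carbon is present). Fractional counts are printed with
#' up to 9 decimals, trailing zeros trimmed, so model files are deterministic
#' and diffable while keeping coefficient-weighted element sums of reloaded
#' models within the 1e-6 balance tolerance.
#'
#' @param f An `elemental_formula`.
#' @return A single formula string; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  cnt <- f$counts
  if (!length(cnt)) return("")
  els <- sort(names(cnt))
  if ("C" %in% els) {
    head <- intersect(c("C", "H"), els)
    els <- c(head, setdiff(els, head))
  }
  piece <- function(e) {
    n <- cnt[[e]]
    if (n == 1) return(e)
    num <- sub("0+$", "", sub("\\.$", "", sprintf("%.9f", n)))
    num <- sub("\\.$", "", num)
    paste0(e, num)
  }
  paste(vapply(els, piece, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  ch <- if (is.na(x$charge)) "?" else format(x$charge)
  cat(sprintf("<formula %s charge=%s>\n",
              if (length(x$counts)) format_formula(x) else "(empty)", ch))
  invisible(x)
}

#' Molar mass of an elemental formula
#'
#' @param f An `elemental_formula`.
#' @param table Atomic mass table; defaults to the bundled IUPAC weights.
#' @return Mass in g/mol; 0 for the empty formula.
#' @export
molar_mass <- function(f, table = atomic_masses()) {
  stopifnot(inherits(f, "elemental_formula"))
  if (!length(f$counts)) return(0)
  missing <- setdiff(names(f$counts), names(table))
  if (length(missing)) {
    bof_error("bofkit_chem_error", sprintf(
      "no atomic mass available for element(s): %s", paste(missing, collapse = ", ")))
  }
  sum(f$counts * table[names(f$counts)])
}

#' Stoichiometry-weighted combination of formulas
#'
#' Element-wise linear combination `sum(coef_i * formula_i)`; negative
#' coefficients subtract (byproducts). The combined charge is the same linear
#' combination, or `NA` if any constituent charge is unknown.
#'
#' @param coefs Numeric vector of coefficients.
#' @param formulas List of `elemental_formula` objects, same length.
#' @param drop_tol Counts with absolute value below this are treated as exact
#'   cancellations and dropped (default `1e-9`).
#' @return An `elemental_formula`.
#' @export
weighted_combine <- function(coefs, formulas, drop_tol = 1e-9) {
  stopifnot(is.numeric(coefs), length(coefs) == length(formulas))
  counts <- numeric(0)
  charge <- 0
  for (i in seq_along(coefs)) {
    f <- formulas[[i]]
    stopifnot(inherits(f, "elemental_formula"))
    for (e in names(f$counts)) {
      counts[e] <- (if (e %in% names(counts)) counts[[e]] else 0) + coefs[i] * f$counts[[e]]
    }
    charge <- charge + coefs[i] * f$charge  # NA propagates
  }
  counts[abs(counts) < drop_tol] <- 0
  if (!is.na(charge) && abs(charge) < drop_tol) charge <- 0
  new_formula(counts, charge)
}
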
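# Elemental formula arithmetic on the element set needed for glycerolipids
# and glycerophospholipids. Deuterium (D) is a distinct element so that
# glycerol-D5 internal standards shift mass without touching H bookkeeping.

.ELEMENTS <- c("C", "H", "D", "N", "O", "P")

# CODATA/IUPAC monoisotopic atomic masses (Da)
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

.ELECTRON_MASS <- 0.00054857990946

#' Create an elemental formula
#'
#' An `elemental_formula` is a named vector of non-negative element counts
#' over C, H, D, N, O, P plus an integer charge. Addition and subtraction are
#' element-wise; subtraction that would drive any count negative is an error,
#' which catches chemically impossible fragmentations early.
#'
#' @param C,H,D,N,O,P non-negative integer element counts.
#' @param charge integer charge (0 for a neutral molecule).
#' @return An object of class `elemental_formula`.
#' @examples
#' water <- elemental_formula(H = 2, O = 1)
#' formula_mass(water)
#' @export
elemental_formula <- function(C = 0, H = 0, D = 0, N = 0, O = 0, P = 0,
                              charge = 0L) {
  counts <- c(C = unname(C), H = unname(H), D = unname(D),
              N = unname(N), O = unname(O), P = unname(P))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = round(counts), charge = as.integer(charge)),
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  body <- paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
  chg <- if (x$charge == 0) "" else if (x$charge > 0) {
    paste0("^", if (x$charge > 1) x$charge else "", "+")
  } else {
    paste0("^", if (x$charge < -1) -x$charge else "", "-")
  }
  paste0(body, chg)
}

#' Combine elemental formulas
#'
#' @param f1,f2 `elemental_formula` objects.
#' @return The element-wise sum/difference; charges add/subtract.
#' @export
formula_add <- function(f1, f2) {
  elemental_formula(
    C = f1$counts["C"] + f2$counts["C"], H = f1$counts["H"] + f2$counts["H"],
    D = f1$counts["D"] + f2$counts["D"], N = f1$counts["N"] + f2$counts["N"],
    O = f1$counts["O"] + f2$counts["O"], P = f1$counts["P"] + f2$counts["P"],
    charge = f1$charge + f2$charge
  )
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  counts <- f1$counts - f2$counts
  if (any(counts < 0)) {
    stop("formula subtraction would produce a negative element count (",
         format(f1), " - ", format(f2), ")", call. = FALSE)
  }
  elemental_formula(
    C = counts["C"], H = counts["H"], D = counts["D"],
    N = counts["N"], O = counts["O"], P = counts["P"],
    charge = f1$charge - f2$charge
  )
}

#' Set the charge of a formula
#' @param f an `elemental_formula`.
#' @param charge integer charge.
#' @return The formula with its charge replaced.
#' @export
formula_charge <- function(f, charge) {
  f$charge <- as.integer(charge)
  f
}

#' Monoisotopic mass or m/z of a formula
#'
#' For a neutral formula (charge 0) returns the monoisotopic mass in Da.
#' For an ion, the electron mass is subtracted per positive charge (added per
#' negative charge) and the result divided by |charge|, giving m/z.
#'
#' @param f an `elemental_formula`.
#' @return Mass or m/z in Da, at full double precision.
#' @export
formula_mass <- function(f) {
  m <- sum(f$counts * .ATOMIC_MASS[names(f$counts)])
  if (f$charge == 0) return(m)
  (m - f$charge * .ELECTRON_MASS) / abs(f$charge)
}

#' Round half-up for instrument export
#'
#' Mass spectrometer acquisition lists print m/z to one decimal with
#' round-half-up semantics (so 253.25 prints 253.3), unlike R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# parse strings like "C17H33O2" or "C3HD5O5P" into a formula (charge 0)
parse_formula_string <- function(s) {
  m <- gregexpr("([CHDNOP])([0-9]*)", s)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: ", s, call. = FALSE)
  }
  parts <- regmatches(s, gregexpr("([CHDNOP])([0-9]*)", s))[[1]]
  counts <- stats::setNames(rep(0, length(.ELEMENTS)), .ELEMENTS)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
    counts[el] <- counts[el] + n
  }
  elemental_formula(C = counts["C"], H = counts["H"], D = counts["D"],
                    N = counts["N"], O = counts["O"], P = counts["P"])
}

# frequently used neutral building blocks
.F_H2O <- function() elemental_formula(H = 2, O = 1)
.F_NH3 <- function() elemental_formula(N = 1, H = 3)
.F_GLYCEROL <- function() elemental_formula(C = 3, H = 8, O = 3)
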
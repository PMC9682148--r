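# Fatty acyl chains in carbons:double-bonds shorthand. Double-bond position
# (delta notation) is deliberately not modelled: the MRM chemistry depends
# only on the elemental composition.

#' Create a fatty acyl chain
#'
#' @param carbons chain length (integer >= 2).
#' @param double_bonds number of C=C double bonds (integer >= 0). Must satisfy
#'   `double_bonds <= carbons/2 - 1` for a chemically valid chain.
#' @return An object of class `fatty_acyl` with fields `carbons` and
#'   `double_bonds`.
#' @examples
#' fatty_acyl(18, 1)       # oleic
#' parse_fa("22:1")        # erucic
#' @export
fatty_acyl <- function(carbons, double_bonds = 0) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2) {
    stop("fatty acyl must have at least 2 carbons", call. = FALSE)
  }
  if (is.na(double_bonds) || double_bonds < 0 ||
      double_bonds > carbons / 2 - 1) {
    stop("invalid chain geometry: ", carbons, ":", double_bonds,
         " (need 0 <= double bonds <= carbons/2 - 1)", call. = FALSE)
  }
  structure(list(carbons = carbons, double_bonds = double_bonds),
            class = "fatty_acyl")
}

#' @rdname fatty_acyl
#' @param x a string like `"18:1"`.
#' @export
parse_fa <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)$", trimws(x)))[[1]]
  if (length(m) != 3) stop("cannot parse fatty acyl: '", x, "'", call. = FALSE)
  fatty_acyl(as.integer(m[2]), as.integer(m[3]))
}

#' @export
format.fatty_acyl <- function(x, ...) paste0(x$carbons, ":", x$double_bonds)

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("FA", format(x), "\n")
  invisible(x)
}

#' Elemental formula of a fatty acyl in a given ionic form
#'
#' The free acid of an n:d chain is C(n)H(2n-2d)O2. The acylium cation
#' \[RCO\]+ is the free acid minus a hydroxide (OH); the carboxylate anion
#' \[RCOO\]- is the free acid minus one proton.
#'
#' @param fa a `fatty_acyl`.
#' @param form one of `"free_acid"`, `"acylium"`, `"carboxylate"`.
#' @return An `elemental_formula` (charged for the ionic forms).
#' @examples
#' fa_formula(parse_fa("17:0"), "acylium")      # C17H33O+
#' fa_formula(parse_fa("18:0"), "carboxylate")  # C18H35O2-
#' @export
fa_formula <- function(fa, form = c("free_acid", "acylium", "carboxylate")) {
  form <- match.arg(form)
  n <- fa$carbons
  h <- 2 * n - 2 * fa$double_bonds
  acid <- elemental_formula(C = n, H = h, O = 2)
  switch(form,
    free_acid = acid,
    acylium = formula_charge(
      formula_subtract(acid, elemental_formula(H = 1, O = 1)), 1L),
    carboxylate = formula_charge(
      formula_subtract(acid, elemental_formula(H = 1)), -1L)
  )
}

# canonical label for an acyl multiset, ascending by carbons then double bonds
fa_sort <- function(fas) {
  key <- vapply(fas, function(f) f$carbons * 100 + f$double_bonds, numeric(1))
  fas[order(key)]
}

#' Canonical composition string
#'
#' Acyl chains sorted ascending by carbons then double bonds, joined by `"_"`
#' (underscore denotes unknown sn-position).
#'
#' @param fas list of `fatty_acyl` objects.
#' @return A single string, e.g. `"18:2_22:1_24:1"`.
#' @export
composition_string <- function(fas) {
  paste(vapply(fa_sort(fas), format, character(1)), collapse = "_")
}
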
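# Lipid species: class + acyl chains (explicit or sum composition) + optional
# glycerol-D5 label. The neutral formula of every supported class is the
# class backbone (fully hydroxylated glycero-head compound) plus the acyl
# free acids, minus one water per ester bond formed.

# backbone = glycerol + condensed headgroup, written as the free polyol:
#   MG/DG/TG            glycerol                      C3H8O3
#   PC/LPC              glycerophosphocholine         C8H20NO6P
#   PE/LPE              glycerophosphoethanolamine    C5H14NO6P
#   PG/LPG              glycerophosphoglycerol        C6H15O8P
#   PI/LPI              glycerophosphoinositol        C9H19O11P
#   PS/LPS              glycerophosphoserine          C6H14NO8P
#   MGDG                glycerol + 1 anhydrogalactose C9H18O8
#   DGDG                glycerol + 2 anhydrogalactose C15H28O13
.CLASS_INFO <- list(
  MG   = list(n_chains = 1L, backbone = "C3H8O3",    polarity = "+", adduct = "[M+NH4]+"),
  DG   = list(n_chains = 2L, backbone = "C3H8O3",    polarity = "+", adduct = "[M+NH4]+"),
  TG   = list(n_chains = 3L, backbone = "C3H8O3",    polarity = "+", adduct = "[M+NH4]+"),
  PC   = list(n_chains = 2L, backbone = "C8H20NO6P", polarity = "-", adduct = "[M+CH3COO]-"),
  PE   = list(n_chains = 2L, backbone = "C5H14NO6P", polarity = "-", adduct = "[M-H]-"),
  PG   = list(n_chains = 2L, backbone = "C6H15O8P",  polarity = "-", adduct = "[M-H]-"),
  PI   = list(n_chains = 2L, backbone = "C9H19O11P", polarity = "-", adduct = "[M-H]-"),
  PS   = list(n_chains = 2L, backbone = "C6H14NO8P", polarity = "-", adduct = "[M-H]-"),
  LPC  = list(n_chains = 1L, backbone = "C8H20NO6P", polarity = "-", adduct = "[M+CH3COO]-"),
  LPE  = list(n_chains = 1L, backbone = "C5H14NO6P", polarity = "-", adduct = "[M-H]-"),
  LPG  = list(n_chains = 1L, backbone = "C6H15O8P",  polarity = "-", adduct = "[M-H]-"),
  LPI  = list(n_chains = 1L, backbone = "C9H19O11P", polarity = "-", adduct = "[M-H]-"),
  LPS  = list(n_chains = 1L, backbone = "C6H14NO8P", polarity = "-", adduct = "[M-H]-"),
  MGDG = list(n_chains = 2L, backbone = "C9H18O8",   polarity = "-", adduct = "[M-H]-"),
  DGDG = list(n_chains = 2L, backbone = "C15H28O13", polarity = "-", adduct = "[M-H]-")
)

#' Supported lipid classes
#' @return Character vector of class abbreviations.
#' @export
lipid_classes <- function() names(.CLASS_INFO)

#' Create a lipid species
#'
#' A species is identified by lipid class, acyl chains (either an explicit
#' unordered multiset or a sum composition `total_c:total_db`), and an
#' optional glycerol-D5 label (five backbone hydrogens replaced by
#' deuterium, as in commercial deuterated internal standards).
#'
#' @param lipid_class class abbreviation, see [lipid_classes()].
#' @param chains list of [fatty_acyl()] objects (explicit composition), or
#'   `NULL` when only the sum composition is known.
#' @param total_c,total_db sum composition; required when `chains` is `NULL`,
#'   otherwise checked for consistency if supplied.
#' @param label `"none"` or `"d5"` (glycerol-D5).
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("TG", total_c = 58, total_db = 5)
#' parse_lipid_name("PC 34:2 (18:2_16:0)")
#' parse_lipid_name("LPC-15:0[D5]")
#' @export
lipid_species <- function(lipid_class, chains = NULL, total_c = NULL,
                          total_db = NULL, label = c("none", "d5")) {
  label <- match.arg(label)
  if (!lipid_class %in% names(.CLASS_INFO)) {
    stop("unknown lipid class: '", lipid_class, "'", call. = FALSE)
  }
  info <- .CLASS_INFO[[lipid_class]]
  if (!is.null(chains)) {
    chains <- fa_sort(chains)
    if (length(chains) != info$n_chains) {
      stop(lipid_class, " requires ", info$n_chains, " acyl chain(s), got ",
           length(chains), call. = FALSE)
    }
    cc <- sum(vapply(chains, function(f) f$carbons, numeric(1)))
    dd <- sum(vapply(chains, function(f) f$double_bonds, numeric(1)))
    if (!is.null(total_c) && (total_c != cc || total_db != dd)) {
      stop("explicit chains (", cc, ":", dd, ") do not match the sum ",
           "composition ", total_c, ":", total_db, call. = FALSE)
    }
    total_c <- cc
    total_db <- dd
  } else {
    if (is.null(total_c) || is.null(total_db)) {
      stop("either explicit chains or a sum composition is required",
           call. = FALSE)
    }
    if (info$n_chains == 1L) {
      # single-chain classes: the sum composition is the chain
      chains <- list(fatty_acyl(total_c, total_db))
    }
  }
  structure(list(lipid_class = lipid_class, chains = chains,
                 total_c = as.integer(total_c),
                 total_db = as.integer(total_db), label = label),
            class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, ...) {
  nm <- paste0(x$lipid_class, " ", x$total_c, ":", x$total_db)
  if (!is.null(x$chains) && length(x$chains) > 1) {
    nm <- paste0(nm, " (", composition_string(x$chains), ")")
  }
  if (x$label == "d5") nm <- paste0(nm, "[D5]")
  nm
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a lipid species shorthand name
#'
#' Accepts `"<CLASS>[-| ]<C>:<DB>"`, optionally followed by an explicit chain
#' list in parentheses with `"_"` (unknown sn-positions) or `"/"` separators,
#' and an optional `"[D5]"` label. `"/"` input is accepted but positional
#' information is discarded; chains are stored as an unordered multiset.
#' Zero-chain placeholders (`"0:0"`) in the chain list are ignored.
#'
#' @param name species name, e.g. `"TG 58:5"`, `"PC 34:2 (18:2_16:0)"`,
#'   `"LPC-15:0[D5]"`.
#' @return A `lipid_species`.
#' @export
parse_lipid_name <- function(name) {
  s <- trimws(name)
  label <- "none"
  if (grepl("\\[D5\\]$", s, ignore.case = TRUE)) {
    label <- "d5"
    s <- trimws(sub("\\[D5\\]$", "", s, ignore.case = TRUE))
  }
  pat <- "^([A-Za-z]+)[- ]([0-9]+):([0-9]+)\\s*(\\(([^)]*)\\))?$"
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) == 0) {
    stop("cannot parse lipid species name: '", name, "'", call. = FALSE)
  }
  cls <- toupper(m[2])
  chains <- NULL
  if (nzchar(m[6])) {
    toks <- strsplit(m[6], "[_/]")[[1]]
    toks <- trimws(toks)
    toks <- toks[toks != "" & toks != "0:0"]
    chains <- lapply(toks, parse_fa)
  }
  lipid_species(cls, chains = chains, total_c = as.integer(m[3]),
                total_db = as.integer(m[4]), label = label)
}

#' Neutral elemental formula of a lipid species
#'
#' Backbone + sum of acyl free acids, minus one H2O per ester bond. For the
#' neutral-lipid classes (MG/DG/TG) the formula depends only on the chain
#' totals, so a sum composition is accepted; polar classes also have
#' total-dependent formulas, but explicit chains are required wherever
#' product-ion chemistry needs chain identities. A glycerol-D5 label
#' substitutes five H for five D.
#'
#' @param species a `lipid_species`.
#' @return The neutral `elemental_formula`.
#' @examples
#' species_formula(parse_lipid_name("DG 44:2 (22:1_22:1)"))  # C47H88O5
#' @export
species_formula <- function(species) {
  info <- .CLASS_INFO[[species$lipid_class]]
  f <- parse_formula_string(info$backbone)
  n <- info$n_chains
  # acyl contribution depends only on totals: C(total_c)H(2c-2db)O(2n)
  acyl <- elemental_formula(C = species$total_c,
                            H = 2 * species$total_c - 2 * species$total_db,
                            O = 2 * n)
  f <- formula_add(f, acyl)
  f <- formula_subtract(f, elemental_formula(H = 2 * n, O = n))
  if (species$label == "d5") {
    f <- formula_add(formula_subtract(f, elemental_formula(H = 5)),
                     elemental_formula(D = 5))
  }
  f
}

# number of chains for a class
class_n_chains <- function(lipid_class) .CLASS_INFO[[lipid_class]]$n_chains

# ionization polarity for a class
class_polarity <- function(lipid_class) .CLASS_INFO[[lipid_class]]$polarity
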
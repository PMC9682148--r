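# Adduct and fragmentation rules defining MRM transitions.
#
# Precursor adducts follow the class rule observed on ESI triple quadrupoles
# for these lipids: neutral glycerolipids ionize as ammonium adducts in
# positive mode; choline-containing classes as acetate adducts in negative
# mode; all other polar classes as [M-H]-.
#
# Product channels:
#   DG/TG  : neutral loss of NH3 + one fatty acid (mono-/diacyl fragment)
#   MG     : acylium cation [RCO]+ (default) or loss of NH3 + glycerol
#            ("dehydration" channel, precursor - NH3 - H2O ... - glycerol
#            leaves the same acylium; the alternative channel monitored for
#            some standards is precursor - NH3 - H2O)
#   polar  : deprotonated acyl side chain (carboxylate anion) of one FA
#   LPS-D5 : glycerophosphate-derived headgroup fragment C3HD5O5P-

.ADDUCTS <- list(
  "[M+NH4]+"    = list(delta = "NH4", charge = 1L),
  "[M+H]+"      = list(delta = "H",   charge = 1L),
  "[M-H]-"      = list(delta = "-H",  charge = -1L),
  "[M+CH3COO]-" = list(delta = "C2H3O2", charge = -1L)
)

# per-class instrument parameter defaults (declustering potential, entrance
# potential, collision energy, collision cell exit potential; volts), as
# optimized for the commercial standards of each class
.INSTRUMENT_DEFAULTS <- list(
  MG   = c(dp = 60,   ep = 10,  ce = 21,  cxp = 14),
  DG   = c(dp = 50,   ep = 10,  ce = 26,  cxp = 18),
  TG   = c(dp = 80,   ep = 10,  ce = 37,  cxp = 24),
  MGDG = c(dp = -80,  ep = -10, ce = -30, cxp = -15),
  DGDG = c(dp = -180, ep = -10, ce = -40, cxp = -15),
  LPC  = c(dp = -40,  ep = -10, ce = -40, cxp = -13),
  LPE  = c(dp = -110, ep = -10, ce = -30, cxp = -13),
  LPG  = c(dp = -100, ep = -10, ce = -34, cxp = -17),
  LPI  = c(dp = -110, ep = -10, ce = -44, cxp = -13),
  LPS  = c(dp = -40,  ep = -10, ce = -34, cxp = -9),
  PC   = c(dp = -65,  ep = -10, ce = -52, cxp = -15),
  PE   = c(dp = -120, ep = -10, ce = -38, cxp = -13),
  PG   = c(dp = -120, ep = -10, ce = -44, cxp = -13),
  PI   = c(dp = -55,  ep = -10, ce = -60, cxp = -15),
  PS   = c(dp = -60,  ep = -10, ce = -50, cxp = -13)
)

adduct_formula <- function(name) {
  a <- .ADDUCTS[[name]]
  if (is.null(a)) stop("unknown adduct: ", name, call. = FALSE)
  a
}

#' Precursor ion of a lipid species
#'
#' Chooses the adduct by class (MG/DG/TG ammonium adduct; PC/LPC acetate
#' adduct; remaining polar classes deprotonated) and computes the
#' monoisotopic m/z with electron-mass correction.
#'
#' @param species a `lipid_species` or shorthand name string.
#' @return A list with `adduct` (name), `formula` (ion `elemental_formula`)
#'   and `mz` (full precision; round with [round_half_up()] for export).
#' @examples
#' precursor_ion("MG 17:0")$mz       # 362.33 -> prints as 362.3
#' precursor_ion("LPC-15:0[D5]")$mz  # acetate adduct, 545.4
#' @export
precursor_ion <- function(species) {
  species <- as_lipid_species(species)
  info <- .CLASS_INFO[[species$lipid_class]]
  a <- adduct_formula(info$adduct)
  neutral <- species_formula(species)
  ion <- if (identical(a$delta, "-H")) {
    formula_subtract(neutral, elemental_formula(H = 1))
  } else if (identical(a$delta, "NH4")) {
    formula_add(neutral, elemental_formula(N = 1, H = 4))
  } else if (identical(a$delta, "H")) {
    formula_add(neutral, elemental_formula(H = 1))
  } else {
    formula_add(neutral, parse_formula_string(a$delta))
  }
  ion <- formula_charge(ion, a$charge)
  list(adduct = info$adduct, formula = ion, mz = formula_mass(ion))
}

as_lipid_species <- function(x) {
  if (inherits(x, "lipid_species")) x else parse_lipid_name(x)
}

# normalize a channel spec into list(type, fa)
parse_channel <- function(channel) {
  if (is.list(channel)) return(channel)
  ch <- trimws(channel)
  if (grepl("^(loss|acyl_loss):", ch)) {
    list(type = "acyl_loss", fa = parse_fa(sub("^[a-z_]+:", "", ch)))
  } else if (grepl("^carboxylate:", ch)) {
    list(type = "carboxylate", fa = parse_fa(sub("^carboxylate:", "", ch)))
  } else if (ch %in% c("acylium", "dehydration", "headgroup_d5")) {
    list(type = ch, fa = NULL)
  } else {
    stop("unknown fragmentation channel: '", channel, "'", call. = FALSE)
  }
}

channel_string <- function(channel) {
  ch <- parse_channel(channel)
  if (is.null(ch$fa)) ch$type
  else paste0(sub("acyl_loss", "loss", ch$type), ":", format(ch$fa))
}

#' Product ion m/z for a fragmentation channel
#'
#' @param species a `lipid_species` or name string.
#' @param channel channel spec: `"loss:<fa>"` (DG/TG neutral loss of NH3 +
#'   fatty acid), `"acylium"` or `"dehydration"` (MG), `"carboxylate:<fa>"`
#'   (polar classes), or `"headgroup_d5"` (D5-labelled LPS glycerophosphate
#'   fragment).
#' @return Product ion m/z (full precision).
#' @examples
#' product_mz("MG 17:0", "acylium")                       # 253.3
#' product_mz("DG 44:2 (22:1_22:1)", "loss:22:1")         # 395.4
#' product_mz("PE-31:1[D5] (14:1_17:0)", "carboxylate:14:1")  # 225.2
#' @export
product_mz <- function(species, channel) {
  species <- as_lipid_species(species)
  ch <- parse_channel(channel)
  cls <- species$lipid_class
  if (ch$type == "acyl_loss") {
    if (!cls %in% c("DG", "TG")) {
      stop("acyl-loss channel is defined for DG/TG only", call. = FALSE)
    }
    check_fa_possible(species, ch$fa)
    prec <- precursor_ion(species)$formula
    frag <- formula_subtract(prec, .F_NH3())
    frag <- formula_subtract(frag, fa_formula(ch$fa, "free_acid"))
    formula_mass(frag)
  } else if (ch$type == "acylium") {
    if (cls != "MG") stop("acylium channel is defined for MG only",
                          call. = FALSE)
    fa <- species$chains[[1]] %||% fatty_acyl(species$total_c,
                                              species$total_db)
    formula_mass(fa_formula(fa, "acylium"))
  } else if (ch$type == "dehydration") {
    if (cls != "MG") stop("dehydration channel is defined for MG only",
                          call. = FALSE)
    prec <- precursor_ion(species)$formula
    formula_mass(formula_subtract(formula_subtract(prec, .F_NH3()), .F_H2O()))
  } else if (ch$type == "carboxylate") {
    if (class_polarity(cls) != "-") {
      stop("carboxylate channel is defined for polar classes only",
           call. = FALSE)
    }
    check_fa_possible(species, ch$fa)
    formula_mass(fa_formula(ch$fa, "carboxylate"))
  } else if (ch$type == "headgroup_d5") {
    if (cls != "LPS" || species$label != "d5") {
      stop("headgroup_d5 channel is defined for D5-labelled LPS only",
           call. = FALSE)
    }
    formula_mass(formula_charge(parse_formula_string("C3HD5O5P"), -1L))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_fa_possible <- function(species, fa) {
  if (!is.null(species$chains)) {
    present <- vapply(species$chains, function(f) {
      f$carbons == fa$carbons && f$double_bonds == fa$double_bonds
    }, logical(1))
    if (!any(present)) {
      stop("FA ", format(fa), " is not part of ", format(species),
           call. = FALSE)
    }
  } else {
    # sum composition: the FA must at least fit inside the totals with
    # valid remaining chains
    n <- class_n_chains(species$lipid_class)
    rem_c <- species$total_c - fa$carbons
    rem_db <- species$total_db - fa$double_bonds
    if (rem_c < 2 * (n - 1) || rem_db < 0) {
      stop("FA ", format(fa), " cannot be part of ", format(species),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a complete MRM transition
#'
#' @param species a `lipid_species` or name string.
#' @param channel fragmentation channel, see [product_mz()].
#' @param params optional named numeric overrides for `dp`, `ep`, `ce`,
#'   `cxp` (volts); class defaults are used otherwise.
#' @param rt_min expected retention time (minutes) for scheduled MRM;
#'   `NA` for unscheduled acquisition.
#' @param rt_window_s scheduled MRM window width in seconds (centred on
#'   `rt_min`).
#' @return One-row data frame with columns `species`, `label`, `channel`,
#'   `q1_mz`, `q3_mz` (one-decimal instrument export values), `q1_exact`,
#'   `q3_exact` (full precision), `polarity`, `dp`, `ep`, `ce`, `cxp`,
#'   `rt_min`, `rt_window_s`.
#' @examples
#' build_transition("MG 17:0", "acylium")
#' @export
build_transition <- function(species, channel, params = NULL, rt_min = NA,
                             rt_window_s = NA) {
  species <- as_lipid_species(species)
  cls <- species$lipid_class
  p <- .INSTRUMENT_DEFAULTS[[cls]]
  if (!is.null(params)) p[names(params)] <- unlist(params)
  prec <- precursor_ion(species)
  q3 <- product_mz(species, channel)
  stopifnot(q3 < prec$mz)
  data.frame(
    species = format(species),
    label = species$label,
    channel = channel_string(channel),
    q1_mz = round_half_up(prec$mz, 1),
    q3_mz = round_half_up(q3, 1),
    q1_exact = prec$mz,
    q3_exact = q3,
    polarity = class_polarity(cls),
    dp = p[["dp"]], ep = p[["ep"]], ce = p[["ce"]], cxp = p[["cxp"]],
    rt_min = rt_min,
    rt_window_s = rt_window_s,
    stringsAsFactors = FALSE
  )
}

#' Transition list for a set of species names
#'
#' Convenience wrapper building the default quantifier transition per
#' species: MG acylium, DG/TG loss of each explicit chain (or error if only
#' a sum composition is given -- use [build_tg_panel()] for sum-composition
#' TG panels), polar classes the carboxylate of the default quantifier FA
#' (the lower-m/z chain unless overridden).
#'
#' @param names character vector of shorthand species names.
#' @param quantifier_fa optional named character vector mapping species name
#'   to the FA quantified (e.g. `c("PC 34:2 (18:2_16:0)" = "18:2")`).
#' @return Data frame of transitions, one or more rows per species.
#' @export
transition_table <- function(names, quantifier_fa = NULL) {
  rows <- lapply(names, function(nm) {
    sp <- parse_lipid_name(nm)
    cls <- sp$lipid_class
    if (cls == "MG") {
      build_transition(sp, "acylium")
    } else if (cls %in% c("DG", "TG")) {
      if (is.null(sp$chains)) {
        stop("explicit chains required for ", nm,
             "; use build_tg_panel() for sum compositions", call. = FALSE)
      }
      fas <- unique(vapply(sp$chains, format, character(1)))
      do.call(rbind, lapply(fas, function(fa) {
        build_transition(sp, paste0("loss:", fa))
      }))
    } else {
      fa <- quantifier_fa[[nm]] %||% default_quantifier_fa(sp)
      if (cls == "LPS" && sp$label == "d5") {
        build_transition(sp, "headgroup_d5")
      } else {
        build_transition(sp, paste0("carboxylate:", fa))
      }
    }
  })
  do.call(rbind, rows)
}

# default quantifier FA for a polar species: the lower-m/z (lighter) chain
default_quantifier_fa <- function(species) {
  if (is.null(species$chains)) {
    stop("explicit chains required to pick a quantifier FA for ",
         format(species), call. = FALSE)
  }
  masses <- vapply(species$chains,
                   function(f) formula_mass(fa_formula(f, "carboxylate")),
                   numeric(1))
  format(species$chains[[which.min(masses)]])
}

#' Write a transition list to CSV
#'
#' Instrument-export dialect: one row per transition, one-decimal m/z.
#'
#' @param transitions data frame from [build_transition()] /
#'   [transition_table()] / [build_tg_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(transitions, path) {
  cols <- c("species", "label", "channel", "q1_mz", "q3_mz", "polarity",
            "dp", "ep", "ce", "cxp", "rt_min", "rt_window_s")
  out <- transitions[, intersect(cols, names(transitions)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
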
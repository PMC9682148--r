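# TG composition enumeration and MRM panel assembly. An isobaric TG sum
# composition (e.g. TG 58:5) can arise from several acyl triplets drawn from
# the fatty-acid pool of the tissue; the acquisition panel must carry one
# acyl-loss transition per distinct FA appearing in any candidate so the
# resolver can later decide which triplet(s) are present.

#' Default fatty-acid pool
#'
#' The fatty acids expected in pennycress (field pennycress, *Thlaspi
#' arvense*) seed and seedling glycerolipids: palmitic through nervonic,
#' including the very-long-chain erucic acid (22:1) characteristic of this
#' oilseed. Override when working with other tissues.
#'
#' @return List of [fatty_acyl()] objects.
#' @export
default_fa_pool <- function() {
  lapply(c("16:0", "18:0", "18:1", "18:2", "18:3",
           "20:0", "20:1", "22:1", "24:1"), parse_fa)
}

fa_pool_validate <- function(pool) {
  if (length(pool) == 0) stop("fatty-acid pool must be non-empty",
                              call. = FALSE)
  keys <- vapply(pool, format, character(1))
  if (anyDuplicated(keys)) stop("fatty-acid pool contains duplicates",
                                call. = FALSE)
  pool
}

#' Enumerate candidate TG acyl compositions
#'
#' All multisets of three pool fatty acids whose summed carbons and double
#' bonds equal the TG sum composition, in canonical order (chains sorted
#' ascending within a composition; compositions sorted lexicographically).
#'
#' @param total_c,total_db TG sum composition.
#' @param pool fatty-acid pool (list of [fatty_acyl()]), default
#'   [default_fa_pool()].
#' @return List of compositions; each is a list of three `fatty_acyl`.
#'   Empty list when no combination fits.
#' @examples
#' comps <- enumerate_tg_compositions(58, 5)
#' sapply(comps, composition_string)
#' @export
enumerate_tg_compositions <- function(total_c, total_db,
                                      pool = default_fa_pool()) {
  pool <- fa_pool_validate(pool)
  n <- length(pool)
  out <- list()
  # combinations with repetition, i <= j <= k, over the pool
  for (i in seq_len(n)) {
    for (j in i:n) {
      ci <- pool[[i]]$carbons + pool[[j]]$carbons
      di <- pool[[i]]$double_bonds + pool[[j]]$double_bonds
      if (ci + 2 > total_c) next
      for (k in j:n) {
        if (ci + pool[[k]]$carbons == total_c &&
            di + pool[[k]]$double_bonds == total_db) {
          out[[length(out) + 1L]] <- fa_sort(list(pool[[i]], pool[[j]],
                                                  pool[[k]]))
        }
      }
    }
  }
  keys <- vapply(out, composition_string, character(1))
  out <- out[order(keys)]
  for (comp in out) {
    stopifnot(sum(vapply(comp, function(f) f$carbons, numeric(1))) == total_c,
              sum(vapply(comp, function(f) f$double_bonds,
                         numeric(1))) == total_db)
  }
  out
}

#' Build the TG acyl-loss MRM panel
#'
#' For each TG sum composition, emits one acyl-loss transition per distinct
#' fatty acid appearing in any candidate composition under the pool.
#' Precursors with no candidate composition are kept in the output with a
#' warning but contribute no product channels.
#'
#' @param tg_species character vector of TG sum-composition names
#'   (`"TG 58:5"`) or list of `lipid_species`.
#' @param pool fatty-acid pool.
#' @return Data frame of transitions (see [build_transition()]) with an
#'   extra column `n_candidates`; canonically ordered and free of duplicate
#'   (q1, q3) pairs.
#' @examples
#' panel <- build_tg_panel(c("TG 58:5", "TG 64:4"))
#' panel[, c("species", "channel", "q1_mz", "q3_mz")]
#' @export
build_tg_panel <- function(tg_species, pool = default_fa_pool()) {
  pool <- fa_pool_validate(pool)
  specs <- lapply(tg_species, as_lipid_species)
  rows <- lapply(specs, function(sp) {
    if (sp$lipid_class != "TG") {
      stop("build_tg_panel expects TG species, got ", format(sp),
           call. = FALSE)
    }
    comps <- enumerate_tg_compositions(sp$total_c, sp$total_db, pool)
    if (length(comps) == 0) {
      warning("no candidate composition for ", format(sp),
              " under the supplied pool; precursor emitted without ",
              "product channels", call. = FALSE)
      tr <- build_transition(lipid_species("TG", total_c = sp$total_c,
                                           total_db = sp$total_db,
                                           label = sp$label),
                             paste0("loss:", format(pool[[1]])))
      # no valid channel: keep the precursor row, blank the product
      tr$q3_mz <- NA_real_
      tr$q3_exact <- NA_real_
      tr$channel <- NA_character_
      tr$n_candidates <- 0L
      return(tr)
    }
    fas <- unique(unlist(lapply(comps, function(cmp) {
      vapply(cmp, format, character(1))
    })))
    fas <- fas[order(vapply(lapply(fas, parse_fa),
                            function(f) f$carbons * 100 + f$double_bonds,
                            numeric(1)))]
    sub <- do.call(rbind, lapply(fas, function(fa) {
      build_transition(lipid_species("TG", total_c = sp$total_c,
                                     total_db = sp$total_db,
                                     label = sp$label),
                       paste0("loss:", fa))
    }))
    sub$n_candidates <- length(comps)
    sub
  })
  panel <- do.call(rbind, rows)
  panel <- panel[!duplicated(panel[, c("q1_mz", "q3_mz")]) |
                   is.na(panel$q3_mz), ]
  rownames(panel) <- NULL
  panel
}

#' Candidate-composition table for TG precursors
#'
#' @param tg_species character vector of TG sum-composition names.
#' @param pool fatty-acid pool.
#' @return Data frame with columns `tg_species`, `composition`,
#'   `n_candidates` (one row per candidate).
#' @export
tg_candidate_table <- function(tg_species, pool = default_fa_pool()) {
  rows <- lapply(tg_species, function(nm) {
    sp <- as_lipid_species(nm)
    comps <- enumerate_tg_compositions(sp$total_c, sp$total_db, pool)
    if (length(comps) == 0) {
      return(data.frame(tg_species = format(sp), composition = NA_character_,
                        n_candidates = 0L, stringsAsFactors = FALSE))
    }
    data.frame(tg_species = format(sp),
               composition = vapply(comps, composition_string, character(1)),
               n_candidates = length(comps), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# class-level default retention times (min) on the HILIC polar method,
# taken from the elution order of the standards
.POLAR_CLASS_RT <- c(MGDG = 2.8, PC = 3.9, DGDG = 4.5, LPC = 5.1, PE = 6.1,
                     LPE = 7.4, PG = 7.4, PI = 8.5, LPG = 8.7, LPI = 9.6,
                     PS = 9.6, LPS = 11.9)

#' Build the scheduled polar-lipid MRM panel
#'
#' One carboxylate-channel transition per species (the quantifier FA is the
#' lower-m/z chain unless overridden), with a scheduled-MRM window centred
#' on the expected retention time. Polar classes elute by headgroup on the
#' HILIC method, so class-level default retention times are used when no
#' species-level time is supplied.
#'
#' @param species character vector of polar species names (explicit chains).
#' @param rt named numeric vector of expected retention times (minutes) per
#'   species name; falls back to class defaults.
#' @param scheduled logical; if `FALSE`, transitions carry no window.
#' @param window_s scheduled MRM window width in seconds.
#' @param quantifier_fa optional named character vector, see
#'   [transition_table()].
#' @return Data frame of transitions with `rt_min` and `rt_window_s` set,
#'   plus `rt_lo`/`rt_hi` window bounds in minutes.
#' @examples
#' build_polar_panel("LPE 18:1", rt = c("LPE 18:1" = 7.5))
#' @export
build_polar_panel <- function(species, rt = NULL, scheduled = TRUE,
                              window_s = 180, quantifier_fa = NULL) {
  rows <- lapply(species, function(nm) {
    sp <- parse_lipid_name(nm)
    if (class_polarity(sp$lipid_class) != "-") {
      stop(nm, " is not a polar class; use build_tg_panel()/",
           "transition_table() for neutral lipids", call. = FALSE)
    }
    rt_i <- if (!is.null(rt) && nm %in% names(rt)) {
      rt[[nm]]
    } else if (scheduled) {
      unname(.POLAR_CLASS_RT[sp$lipid_class])
    } else {
      NA_real_
    }
    if (scheduled && (is.null(rt_i) || is.na(rt_i))) {
      stop("scheduled acquisition requires an expected retention time for ",
           nm, call. = FALSE)
    }
    ch <- if (sp$lipid_class == "LPS" && sp$label == "d5") {
      "headgroup_d5"
    } else {
      fa <- quantifier_fa[[nm]] %||% default_quantifier_fa(sp)
      paste0("carboxylate:", fa)
    }
    tr <- build_transition(sp, ch,
                           rt_min = if (scheduled) rt_i else NA,
                           rt_window_s = if (scheduled) window_s else NA)
    tr$rt_lo <- if (scheduled) rt_i - window_s / 120 else NA_real_
    tr$rt_hi <- if (scheduled) rt_i + window_s / 120 else NA_real_
    tr
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
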
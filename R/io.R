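# File formats and run configuration binding the modules into a workflow.
# The area-table dialect is fixed (tab-delimited, header row = sample ids,
# first column = species id) because vendor export dialects vary.

#' Read / write a wide peak-area table
#'
#' Tab-delimited: first column `species`, one column per sample, one row
#' per molecular species or internal standard.
#'
#' @param path file path.
#' @return Data frame with `species` first.
#' @export
read_area_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "species"
  tab
}

#' @rdname read_area_table
#' @param area_table data frame to write.
#' @export
write_area_table <- function(area_table, path) {
  utils::write.table(area_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable parameters of the workflow with their defaults, so every
#' configuration decision is visible and overridable from one YAML file.
#'
#' @return Named list: `fa_pool` (character), `is_map` (data frame),
#'   `tissue_mg`, `rt_tol`, `ratio_tol`, `mz_decimals`, `rt_window_s`,
#'   `peak_width`, `noise` (list), `seed`.
#' @export
default_run_config <- function() {
  list(
    fa_pool = vapply(default_fa_pool(), format, character(1)),
    is_map = default_is_map(),
    tissue_mg = 10,
    rt_tol = 0.05,
    ratio_tol = c(0.7, 1.4),
    mz_decimals = 1,
    rt_window_s = 180,
    peak_width = 0.08,
    noise = list(baseline_frac = 0.005, shot_cv = 0.02, rt_jitter_sd = 0),
    seed = 1L
  )
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()]; the `is_map` key may
#' be a list of `lipid_class`/`is_species`/`nmol` records. Tolerances must
#' be positive and every referenced species name parseable.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Configuration list as in [default_run_config()].
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (key in names(user)) {
    cfg[[key]] <- if (key == "is_map") {
      do.call(rbind, lapply(user$is_map, function(r) {
        data.frame(lipid_class = r$lipid_class, is_species = r$is_species,
                   nmol = r$nmol, stringsAsFactors = FALSE)
      }))
    } else {
      user[[key]]
    }
  }
  if (cfg$rt_tol <= 0 || any(unlist(cfg$ratio_tol) <= 0) ||
      cfg$rt_window_s <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  for (nm in cfg$is_map$is_species) parse_lipid_name(nm)
  for (fa in cfg$fa_pool) parse_fa(fa)
  cfg
}

#' Write XIC traces to long-format CSV
#'
#' Columns `transition_id`, `rt_min`, `intensity`.
#'
#' @param xics an `xic_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xic_csv <- function(xics, path) {
  rows <- lapply(xics, function(tr) {
    data.frame(transition_id = tr$id, precursor = tr$precursor,
               channel = tr$channel,
               is_standard = isTRUE(tr$is_standard),
               rt_min = tr$rt, intensity = tr$intensity,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read XIC traces from long-format CSV
#'
#' @param path CSV written by [write_xic_csv()] (or matching its layout).
#' @return An `xic_set`.
#' @export
read_xic_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  traces <- lapply(split(tab, tab$transition_id), function(d) {
    d <- d[order(d$rt_min), ]
    structure(list(id = d$transition_id[1], precursor = d$precursor[1],
                   channel = d$channel[1],
                   fa = sub("^loss:", "", d$channel[1]),
                   is_standard = isTRUE(d$is_standard[1]),
                   rt = d$rt_min, intensity = d$intensity),
              class = "xic_trace")
  })
  structure(unname(traces), class = "xic_set")
}
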
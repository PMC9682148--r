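# Regression checking of computed transition chemistry against the
# operator-entered standards panel shipped in inst/extdata. Printed values
# are unit-resolution numbers typed by an operator; a handful of rows drift
# from theory by more than rounding, and those are flagged by computation
# rather than silently passed.

#' The packaged standards MRM panel
#'
#' One-decimal precursor/product transitions for the commercial standards of
#' every supported class, with instrument parameters, expected retention
#' times, and the fragmentation channel implied by each printed product ion.
#' MG 19:0 and MG 21:0 are monitored on the NH3 + H2O loss channel rather
#' than the acylium channel used for the other MG standards.
#'
#' @return Data frame with columns `name`, `species`, `channel`,
#'   `q1_printed`, `q3_printed`, `dp`, `ep`, `ce`, `cxp`, `rt_min`.
#' @export
standards_panel <- function() {
  path <- system.file("extdata", "standards_panel.csv", package = "lipidmrm",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute the standards panel and flag operator drift
#'
#' Recomputes every transition of [standards_panel()] from the species name
#' and channel, and compares with the printed values. Rows whose printed
#' m/z deviates from theory by more than `tol` are flagged as operator
#' drift; the remainder must agree within `tol` (printed values are
#' unit-resolution, so `tol` defaults to 0.15 Da).
#'
#' @param tol tolerance in Da for declaring a printed value consistent with
#'   theory.
#' @return The panel with added columns `q1_calc`, `q3_calc` (exact),
#'   `q1_dev`, `q3_dev` (printed minus calculated) and logical `flagged`.
#' @export
check_standards_panel <- function(tol = 0.15) {
  panel <- standards_panel()
  calc <- lapply(seq_len(nrow(panel)), function(i) {
    sp <- parse_lipid_name(panel$species[i])
    q1 <- precursor_ion(sp)$mz
    q3 <- product_mz(sp, panel$channel[i])
    c(q1 = q1, q3 = q3)
  })
  calc <- do.call(rbind, calc)
  panel$q1_calc <- calc[, "q1"]
  panel$q3_calc <- calc[, "q3"]
  panel$q1_dev <- panel$q1_printed - panel$q1_calc
  panel$q3_dev <- panel$q3_printed - panel$q3_calc
  panel$flagged <- abs(panel$q1_dev) > tol | abs(panel$q3_dev) > tol
  panel
}
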
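# LC-MS method-validation statistics: calibration linearity, limits of
# detection and quantification from signal-to-noise, recovery efficiency
# (standards spiked before vs after extraction) and matrix effect
# (standards in matrix vs neat solvent).

#' Fit a calibration curve
#'
#' Ordinary least-squares line through a serial-dilution series, with LOD
#' and LOQ from the S/N definition (3x and 10x noise over slope). The
#' linear range is found by anchoring the fit on the lowest third of the
#' dilution series and extending upward point by point while each next
#' point stays within 15% relative deviation of the extrapolated line
#' (detector saturation breaks the extension); the reported slope,
#' intercept and R^2 are from the final fit over the linear range, whose
#' lower end is additionally bounded by the LOQ.
#'
#' @param amount standard amounts (fmol, > 0).
#' @param response measured responses (areas or heights).
#' @param noise_sd baseline noise SD on the response scale, used for
#'   LOD/LOQ; `NA` skips the limits.
#' @param max_rel_residual relative-residual bound defining the upper end
#'   of the linear range.
#' @return Object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `lod`, `loq`, `linear_range`, `points`.
#' @examples
#' fit_calibration(c(1, 2, 4, 8), c(2, 4, 8, 16), noise_sd = 0.1)
#' @export
fit_calibration <- function(amount, response, noise_sd = NA,
                            max_rel_residual = 0.15) {
  stopifnot(length(amount) == length(response))
  if (length(amount) < 3) stop("at least 3 calibration points required",
                               call. = FALSE)
  if (any(amount <= 0)) stop("standard amounts must be > 0", call. = FALSE)
  if (stats::sd(amount) == 0) stop("degenerate calibration: all amounts ",
                                   "identical", call. = FALSE)
  if (all(response == 0)) stop("degenerate calibration: all responses zero",
                               call. = FALSE)
  ord <- order(amount)
  amount <- amount[ord]
  response <- response[ord]
  n <- length(amount)
  k <- max(3L, ceiling(n / 3))
  while (k < n) {
    fit_k <- stats::lm(response[1:k] ~ amount[1:k])
    pred <- sum(stats::coef(fit_k) * c(1, amount[k + 1]))
    dev <- abs(response[k + 1] - pred) / max(abs(pred),
                                             .Machine$double.eps)
    if (dev > max_rel_residual) break
    k <- k + 1L
  }
  fit <- stats::lm(response[1:k] ~ amount[1:k])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  y_k <- response[1:k]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y_k - mean(y_k))^2)
  lims <- if (!is.na(noise_sd)) lod_loq(noise_sd, slope) else
    c(lod = NA_real_, loq = NA_real_)
  lo <- if (!is.na(lims[["loq"]])) {
    cand <- amount[1:k][amount[1:k] >= lims[["loq"]]]
    if (length(cand)) min(cand) else NA_real_
  } else {
    amount[1]
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 lod = unname(lims[["lod"]]), loq = unname(lims[["loq"]]),
                 linear_range = c(lo, amount[k]),
                 points = data.frame(amount = amount, response = response)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration: response = %.4g * amount + %.4g (R2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.na(x$lod)) {
    cat(sprintf("LOD %.3g, LOQ %.3g, linear range [%.3g, %.3g]\n",
                x$lod, x$loq, x$linear_range[1], x$linear_range[2]))
  }
  invisible(x)
}

#' Limits of detection and quantification from signal-to-noise
#'
#' LOD and LOQ are the amounts giving signal-to-noise 3 and 10: `3 *
#' noise_sd / slope` and `10 * noise_sd / slope`. Their ratio is exactly
#' 10/3 for any input.
#'
#' @param noise_sd baseline noise SD on the response scale (>= 0).
#' @param slope calibration slope (> 0), response per amount.
#' @return Named vector `c(lod =, loq =)` on the amount scale.
#' @examples
#' lod_loq(3, 1)  # lod 9, loq 30
#' @export
lod_loq <- function(noise_sd, slope) {
  if (is.na(slope) || slope <= 0) stop("calibration slope must be > 0",
                                       call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  c(lod = 3 * noise_sd / slope, loq = 10 * noise_sd / slope)
}

#' Recovery efficiency
#'
#' Ratio of internal-standard signal when spiked before extraction over
#' spiked after extraction, in percent. Replicate vectors are aggregated as
#' a ratio of means.
#'
#' @param is_before IS signal intensity (or replicate vector), spiked
#'   before extraction.
#' @param is_after IS signal intensity (or replicate vector), spiked after
#'   extraction (> 0).
#' @return RE in percent.
#' @examples
#' recovery_efficiency(750, 1000)  # 75
#' @export
recovery_efficiency <- function(is_before, is_after) {
  after <- mean(is_after)
  if (is.na(after) || after <= 0) {
    stop("after-extraction IS intensity must be > 0", call. = FALSE)
  }
  mean(is_before) / after * 100
}

#' Matrix effect
#'
#' Percent deviation of the internal-standard signal in matrix (spiked
#' after extraction) from the neat-solvent signal: `(after/alone)*100 -
#' 100`. Negative values indicate ion suppression, positive enhancement.
#' Replicates aggregate as a ratio of means.
#'
#' @param is_after IS signal in matrix (or replicate vector).
#' @param is_alone IS signal in neat solvent (> 0).
#' @return ME in percent (>= -100).
#' @examples
#' matrix_effect(680, 1000)  # -32
#' @export
matrix_effect <- function(is_after, is_alone) {
  alone <- mean(is_alone)
  if (is.na(alone) || alone <= 0) {
    stop("neat-solvent IS intensity must be > 0", call. = FALSE)
  }
  mean(is_after) / alone * 100 - 100
}

#' Flag validation results against acceptance thresholds
#'
#' Matrix effect outside +/- 25% flags `suppressed`/`enhanced` (boundaries
#' inclusive: ME of exactly -25 or +25 is `ok`); recovery below 75% flags
#' `low_recovery` (75 exactly is `ok`).
#'
#' @param re recovery efficiency in percent (may be `NA`).
#' @param me matrix effect in percent (may be `NA`).
#' @param me_limit,re_limit threshold magnitudes.
#' @return Character vector of flags; `"ok"` when all thresholds pass.
#' @export
validation_flags <- function(re, me, me_limit = 25, re_limit = 75) {
  flags <- character(0)
  if (!is.na(me) && me < -me_limit) flags <- c(flags, "suppressed")
  if (!is.na(me) && me > me_limit) flags <- c(flags, "enhanced")
  if (!is.na(re) && re < re_limit) flags <- c(flags, "low_recovery")
  if (length(flags) == 0) "ok" else paste(flags, collapse = ";")
}

#' Validation report for a set of internal standards
#'
#' @param species character vector of standard names.
#' @param is_before,is_after,is_alone lists of replicate intensity vectors
#'   (or plain numeric vectors of per-standard means), aligned with
#'   `species`.
#' @return Data frame mirroring a method-validation table: `species`,
#'   `me_percent`, `re_percent`, `flag`.
#' @export
validation_report <- function(species, is_before, is_after, is_alone) {
  as_list <- function(x) if (is.list(x)) x else as.list(x)
  is_before <- as_list(is_before)
  is_after <- as_list(is_after)
  is_alone <- as_list(is_alone)
  rows <- lapply(seq_along(species), function(i) {
    re <- recovery_efficiency(is_before[[i]], is_after[[i]])
    me <- matrix_effect(is_after[[i]], is_alone[[i]])
    data.frame(species = species[i], me_percent = me, re_percent = re,
               flag = validation_flags(re, me), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
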
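# Chromatographic peak detection on a single XIC. Replaces vendor peak
# integration: local maxima above a height/signal-to-noise floor, bounds at
# the flanking valleys (or 1% of apex), trapezoidal area.

#' Detect peaks in an XIC trace
#'
#' @param trace an `xic_trace` (list with uniform `rt` grid and
#'   `intensity`), e.g. from [simulate_xics()].
#' @param min_height absolute height floor in counts; peaks below
#'   `max(min_height, min_snr * noise_sd)` are discarded.
#' @param min_snr minimum apex signal-to-noise ratio.
#' @param noise_sd baseline noise SD; estimated from the first differences
#'   of the trace (`mad(diff(y))/sqrt(2)`) when `NULL`.
#' @return Data frame with one row per peak: `transition_id`, `fa`,
#'   `rt_apex`, `height`, `area`, `rt_lo`, `rt_hi`. Zero rows for a flat
#'   trace.
#' @export
detect_peaks <- function(trace, min_height = 0, min_snr = 5,
                         noise_sd = NULL) {
  y <- trace$intensity
  t <- trace$rt
  n <- length(y)
  empty <- data.frame(transition_id = character(0), fa = character(0),
                      rt_apex = numeric(0), height = numeric(0),
                      area = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), stringsAsFactors = FALSE)
  if (n < 3 || max(y) <= 0) return(empty)
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(y)) / sqrt(2)
  }
  baseline <- stats::median(y)
  floor_h <- max(min_height, min_snr * noise_sd, 0)

  apex <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  apex <- apex[y[apex] - baseline >= floor_h]
  if (length(apex) == 0) return(empty)

  rows <- lapply(apex, function(i) {
    h <- y[i]
    # integration bounds: walk outward until the trace returns to baseline
    # (within one noise SD, or 1% of apex) or starts rising into a
    # neighbouring peak
    thresh <- baseline + max(noise_sd, 0.01 * (h - baseline))
    lo <- i
    while (lo > 1 && y[lo - 1] > thresh &&
           y[lo - 1] <= y[lo] + 3 * noise_sd) lo <- lo - 1
    hi <- i
    while (hi < n && y[hi + 1] > thresh &&
           y[hi + 1] <= y[hi] + 3 * noise_sd) hi <- hi + 1
    idx <- lo:hi
    # trapezoid over the bounds after subtracting the trace-wide baseline
    # estimate; clamping at zero keeps noise excursions from going negative
    yc <- pmax(y[idx] - baseline, 0)
    area <- sum(diff(t[idx]) * (utils::head(yc, -1) + utils::tail(yc, -1)) / 2)
    data.frame(transition_id = trace$id %||% NA_character_,
               fa = trace$fa %||% NA_character_,
               rt_apex = t[i], height = h - baseline, area = area,
               rt_lo = t[lo], rt_hi = t[hi], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # merge shoulder artefacts: keep the higher apex of overlapping windows
  out <- out[order(out$rt_apex), , drop = FALSE]
  rownames(out) <- NULL
  out
}
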
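# The TG composition resolver: overlay the acyl-loss XICs of one TG
# precursor, group channels whose peaks co-elute, decide which candidate
# acyl triplet(s) the channel pattern supports (channel height is
# proportional to the multiplicity of that FA in the triplet, assuming
# equal response factors), and select a single multiplicity-corrected
# quantifier transition per resolved species so no precursor peak is
# counted more than once.

#' Group detected peaks by co-elution
#'
#' Single-linkage clustering of peak apexes (all channels of one precursor)
#' on retention time: peaks whose apexes are within `rt_tol` of the nearest
#' cluster member join that cluster. Consensus RT is the height-weighted
#' mean of member apexes.
#'
#' @param peaks data frame from [detect_peaks()] rows of all channels of
#'   one precursor (columns `fa`, `rt_apex`, `height`, `area`,
#'   `transition_id`).
#' @param rt_tol co-elution tolerance in minutes.
#' @return List of groups, each a list with `peaks` (the member rows) and
#'   `rt` (consensus retention time).
#' @export
group_by_coelution <- function(peaks, rt_tol = 0.05) {
  if (nrow(peaks) == 0) return(list())
  peaks <- peaks[order(peaks$rt_apex), , drop = FALSE]
  gap <- c(Inf, diff(peaks$rt_apex))
  gid <- cumsum(gap > rt_tol)
  lapply(split(peaks, gid), function(p) {
    list(peaks = p, rt = sum(p$rt_apex * p$height) / sum(p$height))
  })
}

#' Call acyl compositions for one co-elution group
#'
#' A candidate triplet is *supported* when every distinct FA of the triplet
#' has a co-eluting peak. The per-FA multiplicity is then inferred from the
#' channel heights: since the three acyl chains of a TG are split across
#' the distinct channels, the unit (multiplicity-1) height is the summed
#' candidate-channel height divided by three, and each channel's
#' height/unit ratio is matched to the nearest integer in 1..3. A call is
#' `confirmed` when the inferred multiplicities equal the candidate's chain
#' counts with every ratio inside `ratio_tol` times its integer, and
#' `tentative` when the candidate is supported on presence but the ratios
#' do not match. Ambiguous groups may return several calls.
#'
#' @param group one group from [group_by_coelution()].
#' @param candidates list of candidate compositions from
#'   [enumerate_tg_compositions()].
#' @param ratio_tol two-element numeric: a ratio r supports multiplicity m
#'   when `r/m` lies within `[ratio_tol[1], ratio_tol[2]]`.
#' @return Data frame with one row per call: `composition`, `rt_min`,
#'   `confidence`, `n_channels`; the per-channel evidence (fa, height,
#'   multiplicity, transition_id, area) is attached as a list column
#'   `evidence`. Zero rows (with a warning) when no candidate is supported.
#' @export
call_compositions <- function(group, candidates, ratio_tol = c(0.7, 1.4)) {
  peaks <- group$peaks
  # one evidence row per channel: tallest member peak of that FA
  peaks <- do.call(rbind, lapply(split(peaks, peaks$fa), function(p) {
    p[which.max(p$height), , drop = FALSE]
  }))
  # unit (multiplicity-1) height from the whole group: the three chains of
  # the precursor are spread over ALL co-eluting channels, so a candidate
  # leaving large channels unexplained cannot match its expected ratios
  unit <- sum(peaks$height) / 3
  calls <- list()
  for (cmp in candidates) {
    fas <- vapply(cmp, format, character(1))
    counts <- table(fas)
    if (!all(names(counts) %in% peaks$fa)) next
    ev <- peaks[match(names(counts), peaks$fa), , drop = FALSE]
    ratio <- ev$height / unit
    m <- pmin(pmax(round(ratio), 1L), 3L)
    ok <- all(m == as.integer(counts)) &&
      all(ratio / m >= ratio_tol[1] & ratio / m <= ratio_tol[2])
    ev$multiplicity <- as.integer(counts)
    call <- data.frame(composition = composition_string(cmp),
                       rt_min = group$rt,
                       confidence = if (ok) "confirmed" else "tentative",
                       n_channels = nrow(ev), stringsAsFactors = FALSE)
    call$evidence <- list(ev)
    calls[[length(calls) + 1L]] <- call
  }
  if (length(calls) == 0) {
    warning("co-elution group at ", sprintf("%.2f", group$rt),
            " min supports no candidate composition", call. = FALSE)
    out <- data.frame(composition = character(0), rt_min = numeric(0),
                      confidence = character(0), n_channels = integer(0),
                      stringsAsFactors = FALSE)
    out$evidence <- list()
    return(out)
  }
  do.call(rbind, calls)
}

#' Select one quantifier transition per composition call
#'
#' Each resolved species must be quantified by exactly one of its acyl-loss
#' transitions, divided by the multiplicity of that FA in the triplet so
#' repeated chains are not double-counted. Channel preference: transitions
#' whose FA is unique to the call among all calls of the same precursor
#' come first, then lower multiplicity, with ties broken deterministically
#' by lower product m/z (loss of the heavier FA). Every (transition, peak)
#' pair quantifies at most one call; a call whose channels are all claimed
#' by other calls is left without a quantifier and demoted to tentative —
#' shared-channel area is never split.
#'
#' @param calls data frame of calls for one precursor (all co-elution
#'   groups), as returned by [call_compositions()], with `evidence` list
#'   column.
#' @return The calls with added columns `quantifier_fa`,
#'   `quantifier_transition`, `divisor`, `area_raw`, `area_corrected`.
#' @export
select_quantifiers <- function(calls) {
  n <- nrow(calls)
  cols <- list(quantifier_fa = NA_character_,
               quantifier_transition = NA_character_,
               divisor = NA_integer_, area_raw = NA_real_,
               area_corrected = NA_real_)
  for (nm in names(cols)) calls[[nm]] <- rep(cols[[nm]], length.out = max(n, 1))[seq_len(n)]
  if (n == 0) return(calls)

  fa_usage <- table(unlist(lapply(calls$evidence, function(ev) unique(ev$fa))))
  claimed <- character(0)  # "fa@rt" peak keys already used
  # resolve confirmed calls first, then by descending evidence height
  ord <- order(calls$confidence != "confirmed",
               -vapply(calls$evidence, function(ev) max(ev$height),
                       numeric(1)))
  for (i in ord) {
    ev <- calls$evidence[[i]]
    shared <- fa_usage[ev$fa] > 1
    fa_mass <- vapply(ev$fa, function(f) {
      formula_mass(fa_formula(parse_fa(f), "free_acid"))
    }, numeric(1))
    pref <- order(shared, ev$multiplicity, -fa_mass)
    picked <- FALSE
    for (j in pref) {
      key <- paste0(ev$fa[j], "@", sprintf("%.4f", ev$rt_apex[j]))
      if (key %in% claimed) next
      claimed <- c(claimed, key)
      calls$quantifier_fa[i] <- ev$fa[j]
      calls$quantifier_transition[i] <- ev$transition_id[j]
      calls$divisor[i] <- ev$multiplicity[j]
      calls$area_raw[i] <- ev$area[j]
      calls$area_corrected[i] <- ev$area[j] / ev$multiplicity[j]
      picked <- TRUE
      break
    }
    if (!picked) calls$confidence[i] <- "tentative"
  }
  calls
}

#' Resolve TG acyl compositions from a set of XIC traces
#'
#' End-to-end resolver: detects peaks per transition, groups co-eluting
#' channels per precursor, calls candidate compositions, and selects
#' multiplicity-corrected quantifier transitions. Internal-standard traces
#' (`is_standard = TRUE`) are integrated but not resolved; their areas are
#' returned separately for normalization.
#'
#' @param xics an `xic_set` from [simulate_xics()] (or a list of
#'   `xic_trace` objects with `precursor`/`fa` tags).
#' @param pool fatty-acid pool used for candidate enumeration.
#' @param rt_tol co-elution tolerance (minutes).
#' @param ratio_tol multiplicity ratio acceptance band.
#' @param min_height,min_snr,noise_sd peak-detection settings, see
#'   [detect_peaks()].
#' @return A list with `calls` (data frame: `tg_species`, `composition`,
#'   `rt_min`, `confidence`, `quantifier_fa`, `quantifier_transition`,
#'   `divisor`, `area_raw`, `area_corrected`) and `is_areas` (data frame
#'   `transition_id`, `area` for internal-standard channels).
#' @export
resolve_tg_xics <- function(xics, pool = default_fa_pool(), rt_tol = 0.05,
                            ratio_tol = c(0.7, 1.4), min_height = 0,
                            min_snr = 5, noise_sd = NULL) {
  is_std <- vapply(xics, function(tr) isTRUE(tr$is_standard), logical(1))
  is_areas <- do.call(rbind, lapply(xics[is_std], function(tr) {
    p <- detect_peaks(tr, min_height = min_height, min_snr = min_snr,
                      noise_sd = noise_sd)
    if (nrow(p) == 0) {
      return(data.frame(transition_id = tr$id, area = 0,
                        stringsAsFactors = FALSE))
    }
    data.frame(transition_id = tr$id, area = p$area[which.max(p$height)],
               stringsAsFactors = FALSE)
  }))

  sample_traces <- xics[!is_std]
  precs <- vapply(sample_traces, function(tr) tr$precursor, character(1))
  out <- list()
  for (prec in unique(precs)) {
    traces <- sample_traces[precs == prec]
    peaks <- do.call(rbind, lapply(traces, detect_peaks,
                                   min_height = min_height,
                                   min_snr = min_snr, noise_sd = noise_sd))
    if (is.null(peaks) || nrow(peaks) == 0) next
    sp <- parse_lipid_name(prec)
    candidates <- enumerate_tg_compositions(sp$total_c, sp$total_db, pool)
    groups <- group_by_coelution(peaks, rt_tol = rt_tol)
    calls <- do.call(rbind, lapply(groups, call_compositions,
                                   candidates = candidates,
                                   ratio_tol = ratio_tol))
    if (is.null(calls) || nrow(calls) == 0) next
    calls <- select_quantifiers(calls)
    calls <- cbind(data.frame(tg_species = prec, stringsAsFactors = FALSE),
                   calls)
    out[[length(out) + 1L]] <- calls
  }
  calls <- if (length(out)) do.call(rbind, out) else {
    data.frame(tg_species = character(0), composition = character(0),
               rt_min = numeric(0), confidence = character(0),
               n_channels = integer(0), quantifier_fa = character(0),
               quantifier_transition = character(0), divisor = integer(0),
               area_raw = numeric(0), area_corrected = numeric(0),
               stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  list(calls = calls, is_areas = is_areas)
}

#' Write resolver calls to CSV
#'
#' @param calls calls data frame from [resolve_tg_xics()].
#' @param path output path.
#' @param sample optional sample id written as the first column.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path, sample = NA_character_) {
  out <- cbind(data.frame(sample = sample, stringsAsFactors = FALSE),
               calls[, setdiff(names(calls), "evidence"), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Overlay plot of the acyl-loss channels of one TG precursor
#'
#' Colour-coded XIC overlay of all channels sharing one precursor, the
#' figure used to decide TG acyl compositions by eye.
#'
#' @param xics an `xic_set`.
#' @param precursor precursor sum-composition name, e.g. `"TG 58:5"`.
#' @param calls optional calls data frame; resolved compositions are drawn
#'   as labelled vertical guides.
#' @return Invisibly, the traces plotted.
#' @export
plot_xic_overlay <- function(xics, precursor, calls = NULL) {
  traces <- Filter(function(tr) identical(tr$precursor, precursor), xics)
  if (length(traces) == 0) stop("no traces for ", precursor, call. = FALSE)
  cols <- grDevices::hcl.colors(max(3, length(traces)), "Dark 3")
  ymax <- max(vapply(traces, function(tr) max(tr$intensity), numeric(1)))
  graphics::plot(NA, xlim = range(traces[[1]]$rt), ylim = c(0, 1.05 * ymax),
                 xlab = "retention time (min)", ylab = "intensity (counts)",
                 main = precursor)
  for (i in seq_along(traces)) {
    graphics::lines(traces[[i]]$rt, traces[[i]]$intensity, col = cols[i],
                    lwd = 2)
  }
  graphics::legend("topright",
                   legend = vapply(traces, function(tr) tr$channel,
                                   character(1)),
                   col = cols[seq_along(traces)], lwd = 2, bty = "n")
  if (!is.null(calls) && nrow(calls) > 0) {
    sel <- calls$tg_species == precursor
    graphics::abline(v = calls$rt_min[sel], lty = 3, col = "grey40")
    graphics::text(calls$rt_min[sel], ymax, calls$composition[sel],
                   pos = 3, cex = 0.7, xpd = NA)
  }
  invisible(traces)
}
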
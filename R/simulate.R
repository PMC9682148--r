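# Synthetic MRM data generator. Emulates the structure the TG resolver
# relies on: all acyl-loss channels of one molecular species co-elute as
# Gaussian peaks at the species retention time, with channel height
# proportional to abundance times the multiplicity of that fatty acid in
# the acyl triplet (equal response factors across channels). Baseline and
# shot noise are additive Gaussian; everything is reproducible under a
# fixed seed.

#' Noise parameters for the XIC simulator
#'
#' @param baseline_frac constant baseline as a fraction of the largest
#'   simulated peak height (default 0.5%).
#' @param shot_cv coefficient of variation of the Gaussian shot term
#'   applied per time point, relative to the signal.
#' @param rt_jitter_sd retention-time jitter SD (minutes) applied per
#'   channel; 0 = ideal co-elution.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(baseline_frac = 0.005, shot_cv = 0.02,
                         rt_jitter_sd = 0) {
  structure(list(baseline_frac = baseline_frac, shot_cv = shot_cv,
                 rt_jitter_sd = rt_jitter_sd), class = "noise_params")
}

#' Define a synthetic sample (ground truth)
#'
#' @param species data frame with columns `name` (species shorthand with
#'   explicit chains, e.g. `"TG 58:5 (18:2_18:2_22:1)"`) and `nmol`
#'   (abundance, >= 0).
#' @param tissue_mg tissue dry mass in mg (> 0).
#' @param is_spikes named numeric vector of internal-standard spike amounts
#'   in nmol, named by IS species shorthand.
#' @param seed integer RNG seed attached to the sample.
#' @return Object of class `synthetic_sample`.
#' @export
synthetic_sample <- function(species, tissue_mg = 10,
                             is_spikes = c("TG 49:1 (16:0_17:1_16:0)[D5]" = 0.5),
                             seed = 1L) {
  stopifnot(is.data.frame(species), all(c("name", "nmol") %in% names(species)))
  if (any(species$nmol < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (tissue_mg <= 0) stop("tissue mass must be > 0", call. = FALSE)
  structure(list(species = species, tissue_mg = tissue_mg,
                 is_spikes = is_spikes, seed = as.integer(seed)),
            class = "synthetic_sample")
}

#' Draw a random synthetic TG sample
#'
#' Samples `n_species` distinct TG acyl compositions from the pool
#' (triplets drawn uniformly from multisets of three pool FAs) with
#' log-uniform abundances, emulating the spread of storage-lipid levels in
#' an oilseed extract.
#'
#' @param n_species number of distinct TG compositions.
#' @param pool fatty-acid pool.
#' @param nmol_range abundance range (nmol), sampled log-uniformly. The
#'   default spans a 20-fold range chosen so that every simulated channel
#'   stays above the limit of quantification implied by the default
#'   baseline noise.
#' @param tissue_mg,is_spikes,seed see [synthetic_sample()].
#' @return A `synthetic_sample`.
#' @export
random_tg_sample <- function(n_species = 10, pool = default_fa_pool(),
                             nmol_range = c(0.25, 5), tissue_mg = 10,
                             is_spikes = c("TG 49:1 (16:0_17:1_16:0)[D5]" = 0.5),
                             seed = 1L) {
  set.seed(seed)
  keys <- character(0)
  comps <- list()
  while (length(comps) < n_species) {
    idx <- sort(sample.int(length(pool), 3, replace = TRUE))
    cmp <- fa_sort(pool[idx])
    key <- composition_string(cmp)
    if (key %in% keys) next
    keys <- c(keys, key)
    comps[[length(comps) + 1L]] <- cmp
  }
  names <- vapply(comps, function(cmp) {
    tc <- sum(vapply(cmp, function(f) f$carbons, numeric(1)))
    tdb <- sum(vapply(cmp, function(f) f$double_bonds, numeric(1)))
    paste0("TG ", tc, ":", tdb, " (", composition_string(cmp), ")")
  }, character(1))
  nmol <- exp(stats::runif(n_species, log(nmol_range[1]), log(nmol_range[2])))
  synthetic_sample(data.frame(name = names, nmol = nmol,
                              stringsAsFactors = FALSE),
                   tissue_mg = tissue_mg, is_spikes = is_spikes, seed = seed)
}

# default detector response: counts of peak height per nmol of species for
# a multiplicity-1 channel
.RESPONSE_HEIGHT <- 1e5
# default chromatographic peak width (Gaussian SD, minutes)
.PEAK_WIDTH <- 0.08

#' Simulate XIC traces for a synthetic sample
#'
#' For every ground-truth species, each acyl-loss channel of its composition
#' receives a Gaussian peak at the predicted retention time with height
#' `nmol * multiplicity * response`; channels are ideally co-eluting unless
#' RT jitter is enabled. Internal-standard species are simulated the same
#' way and tagged. Traces for panel transitions matching no ground-truth
#' species stay at baseline.
#'
#' @param sample a [synthetic_sample()].
#' @param panel optional TG panel data frame from [build_tg_panel()]; by
#'   default the panel implied by the ground-truth species (their distinct
#'   FA channels) plus the IS channels is used.
#' @param model a [retention_model()] for TG.
#' @param noise a [noise_params()] object, or `NULL` for noise-free traces.
#' @param peak_width Gaussian peak SD in minutes.
#' @param response peak height (counts) per nmol for a multiplicity-1
#'   channel.
#' @param time_range,time_step chromatographic time grid (minutes).
#' @param seed RNG seed; defaults to the sample's seed.
#' @return A list of class `xic_set`; each element is an `xic_trace` with
#'   fields `id`, `precursor` (sum-composition name), `channel`, `fa`,
#'   `is_standard`, `rt` and `intensity`.
#' @export
simulate_xics <- function(sample, panel = NULL,
                          model = retention_model("TG"),
                          noise = noise_params(), peak_width = .PEAK_WIDTH,
                          response = .RESPONSE_HEIGHT,
                          time_range = NULL, time_step = 0.02,
                          seed = sample$seed) {
  set.seed(seed)
  truth <- lapply(sample$species$name, parse_lipid_name)
  is_truth <- lapply(names(sample$is_spikes), parse_lipid_name)
  all_sp <- c(truth, is_truth)
  all_nmol <- c(sample$species$nmol, unname(sample$is_spikes))
  is_flag <- c(rep(FALSE, length(truth)), rep(TRUE, length(is_truth)))
  bad <- vapply(all_sp, function(s) is.null(s$chains), logical(1))
  if (any(bad)) stop("simulate_xics requires explicit chains for every ",
                     "species", call. = FALSE)

  rts <- vapply(all_sp, predict_rt, numeric(1), model = model)
  if (is.null(time_range)) {
    time_range <- c(max(0, min(rts) - 1.5), max(rts) + 1.5)
  }
  grid <- seq(time_range[1], time_range[2], by = time_step)

  # channels to simulate: per precursor sum composition, the union of FA
  # channels over the panel (if given) and the ground truth
  chan_key <- function(prec, fa) paste0(prec, "|loss:", fa)
  channels <- new.env(parent = emptyenv())
  add_channel <- function(prec, fa, is_std) {
    key <- chan_key(prec, fa)
    if (!is.null(channels[[key]])) return()
    channels[[key]] <- list(precursor = prec, fa = fa, is_standard = is_std)
  }
  prec_name <- function(sp) {
    paste0("TG ", sp$total_c, ":", sp$total_db,
           if (sp$label == "d5") "[D5]" else "")
  }
  for (i in seq_along(all_sp)) {
    sp <- all_sp[[i]]
    if (sp$lipid_class != "TG") {
      warning("skipping non-TG species ", format(sp), call. = FALSE)
      next
    }
    for (fa in unique(vapply(sp$chains, format, character(1)))) {
      add_channel(prec_name(sp), fa, is_flag[i])
    }
  }
  if (!is.null(panel)) {
    ok <- !is.na(panel$channel)
    for (i in which(ok)) {
      add_channel(sub(" \\(.*\\)", "", panel$species[i]),
                  sub("^loss:", "", panel$channel[i]), FALSE)
    }
  }

  keys <- sort(ls(channels))
  signals <- lapply(keys, function(key) numeric(length(grid)))
  names(signals) <- keys

  jit <- noise$rt_jitter_sd %||% 0
  for (i in seq_along(all_sp)) {
    sp <- all_sp[[i]]
    if (sp$lipid_class != "TG") next
    fas <- vapply(sp$chains, format, character(1))
    counts <- table(fas)
    rt0 <- rts[i]
    for (fa in names(counts)) {
      key <- chan_key(prec_name(sp), fa)
      rt_i <- rt0 + if (!is.null(noise) && jit > 0) stats::rnorm(1, 0, jit) else 0
      h <- all_nmol[i] * as.integer(counts[[fa]]) * response
      signals[[key]] <- signals[[key]] +
        h * exp(-0.5 * ((grid - rt_i) / peak_width)^2)
    }
  }

  max_h <- max(c(0, vapply(signals, max, numeric(1))))
  traces <- lapply(keys, function(key) {
    info <- channels[[key]]
    y <- signals[[key]]
    if (!is.null(noise) && max_h > 0) {
      b0 <- noise$baseline_frac * max_h
      y <- y + b0 +
        stats::rnorm(length(y), 0, b0 * 0.25 + noise$shot_cv * y)
      y[y < 0] <- 0
    }
    structure(list(id = key, precursor = info$precursor,
                   channel = paste0("loss:", info$fa), fa = info$fa,
                   is_standard = info$is_standard,
                   rt = grid, intensity = y),
              class = "xic_trace")
  })
  structure(traces, class = "xic_set",
            seed = seed, peak_width = peak_width, response = response)
}

#' @export
print.xic_trace <- function(x, ...) {
  cat("XIC", x$id, ":", length(x$rt), "points,",
      sprintf("max %.3g", max(x$intensity)), "\n")
  invisible(x)
}

#' Simulate an integrated peak-area table
#'
#' Wide table of integrated areas as exported from peak-integration
#' software: one row per molecular species (plus one row per internal
#' standard), one column per sample. Areas equal the analytic integral of
#' the species' simulated quantifier peak (`height * width * sqrt(2*pi)`),
#' with multiplicative noise at the simulator's shot CV.
#'
#' @param samples list of [synthetic_sample()] objects (one per column);
#'   names are used as sample ids.
#' @param noise a [noise_params()] or `NULL` for exact areas.
#' @param peak_width,response as in [simulate_xics()].
#' @param seed RNG seed.
#' @return Data frame; first column `species`, remaining columns one per
#'   sample.
#' @export
simulate_area_table <- function(samples, noise = noise_params(),
                                peak_width = .PEAK_WIDTH,
                                response = .RESPONSE_HEIGHT, seed = 1L) {
  set.seed(seed)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  area_unit <- response * peak_width * sqrt(2 * pi)
  all_rows <- unique(unlist(lapply(samples, function(s) {
    c(s$species$name, names(s$is_spikes))
  })))
  out <- data.frame(species = all_rows, stringsAsFactors = FALSE)
  for (nm in names(samples)) {
    s <- samples[[nm]]
    amounts <- stats::setNames(s$species$nmol, s$species$name)
    amounts[names(s$is_spikes)] <- s$is_spikes
    a <- unname(amounts[all_rows])
    a[is.na(a)] <- 0
    area <- a * area_unit
    if (!is.null(noise)) {
      area <- area * (1 + stats::rnorm(length(area), 0, noise$shot_cv))
      area[area < 0] <- 0
    }
    out[[nm]] <- area
  }
  out
}
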
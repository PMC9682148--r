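# Internal-standard quantification: single-point normalization of
# integrated peak areas against the spiked class standard, scaled by tissue
# mass, with class totals, molecular-species distributions and fatty-acid
# mol% derived from resolved TG compositions.

#' Default internal-standard map
#'
#' One spiked standard per lipid class (a mid-chain member of the
#' commercial standards set for each class). The mapping is a default for
#' simulated work; for real data supply the map actually spiked.
#'
#' @param nmol spike amount applied to every class (single number or named
#'   per-class vector).
#' @return Data frame with columns `lipid_class`, `is_species`, `nmol`.
#' @export
default_is_map <- function(nmol = 0.5) {
  cls <- c("MG", "DG", "TG", "MGDG", "DGDG", "LPC", "LPE", "LPG", "LPI",
           "LPS", "PC", "PE", "PG", "PI", "PS")
  is_sp <- c("MG 17:0", "DG 33:1 (16:1_17:0)[D5]",
             "TG 49:1 (16:0_17:1_16:0)[D5]", "MGDG 34:0 (16:0_18:0)",
             "DGDG 36:0 (18:0_18:0)", "LPC 17:0[D5]", "LPE 17:0[D5]",
             "LPG 17:0[D5]", "LPI 17:0[D5]", "LPS 17:0[D5]",
             "PC 33:1 (16:1_17:0)[D5]", "PE 33:1 (16:1_17:0)[D5]",
             "PG 33:1 (16:1_17:0)[D5]", "PI 33:1 (16:1_17:0)[D5]",
             "PS 33:1 (16:1_17:0)[D5]")
  amt <- if (length(nmol) == 1) rep(nmol, length(cls)) else unname(nmol[cls])
  data.frame(lipid_class = cls, is_species = is_sp, nmol = amt,
             stringsAsFactors = FALSE)
}

#' Normalize a peak area to nmol per mg tissue
#'
#' `area * is_nmol / is_area / tissue_mg`: the area is scaled by the spiked
#' amount of the class internal standard over its integrated area, then by
#' tissue dry mass. Vectorized over `area`.
#'
#' @param area integrated peak area(s) of the analyte.
#' @param is_area integrated peak area of the class internal standard
#'   (> 0).
#' @param is_nmol spiked amount of the internal standard (nmol).
#' @param tissue_mg tissue dry mass (mg, > 0).
#' @param context optional label (sample/class) used in error messages.
#' @return Amount(s) in nmol per mg.
#' @examples
#' normalize_species(2e5, 1e5, 1, 10)  # 0.02 nmol/mg
#' @export
normalize_species <- function(area, is_area, is_nmol, tissue_mg,
                              context = NULL) {
  if (is.na(is_area) || is_area <= 0) {
    stop("internal-standard area must be > 0",
         if (!is.null(context)) paste0(" (", context, ")"), call. = FALSE)
  }
  if (tissue_mg <= 0) stop("tissue mass must be > 0", call. = FALSE)
  area * is_nmol / is_area / tissue_mg
}

#' Quantify a wide area table against class internal standards
#'
#' @param area_table data frame as from [simulate_area_table()] or
#'   [read_area_table()]: first column `species` (shorthand names; internal
#'   standards appear as their own rows), remaining columns one per sample.
#' @param is_map data frame `lipid_class`, `is_species`, `nmol`
#'   ([default_is_map()]).
#' @param tissue_mg named numeric vector of tissue masses per sample (or a
#'   single mass used for all).
#' @return Tidy data frame: `sample`, `lipid_class`, `species`,
#'   `nmol_per_mg`. Internal-standard rows are consumed for normalization
#'   and not reported as analytes.
#' @export
quantify_areas <- function(area_table, is_map = default_is_map(),
                           tissue_mg = 10) {
  stopifnot(names(area_table)[1] == "species")
  samples <- names(area_table)[-1]
  if (length(tissue_mg) == 1) {
    tissue_mg <- stats::setNames(rep(tissue_mg, length(samples)), samples)
  }
  cls_of <- vapply(area_table$species,
                   function(nm) parse_lipid_name(nm)$lipid_class,
                   character(1))
  is_rows <- match(is_map$is_species, area_table$species)
  analyte <- setdiff(seq_len(nrow(area_table)),
                     is_rows[!is.na(is_rows)])
  out <- list()
  for (smp in samples) {
    for (i in analyte) {
      cls <- cls_of[i]
      k <- match(cls, is_map$lipid_class)
      if (is.na(k)) {
        stop("no internal standard mapped for class ", cls, call. = FALSE)
      }
      j <- is_rows[k]
      if (is.na(j)) {
        stop("internal-standard row '", is_map$is_species[k],
             "' missing from the area table (class ", cls, ")",
             call. = FALSE)
      }
      amt <- normalize_species(area_table[[smp]][i], area_table[[smp]][j],
                               is_map$nmol[k], tissue_mg[[smp]],
                               context = paste0("sample ", smp, ", class ",
                                                cls))
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, lipid_class = cls, species = area_table$species[i],
        nmol_per_mg = amt, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class totals with replicate mean and SD
#'
#' Species amounts are summed within sample and class, then averaged across
#' samples (replicates); SD is the sample (n-1) standard deviation, empty
#' for a single replicate.
#'
#' @param quant tidy data frame from [quantify_areas()].
#' @return Data frame `lipid_class`, `mean_nmol_per_mg`, `sd_nmol_per_mg`,
#'   `n`.
#' @export
class_totals <- function(quant) {
  per_sample <- stats::aggregate(nmol_per_mg ~ lipid_class + sample,
                                 data = quant, FUN = sum)
  agg <- stats::aggregate(nmol_per_mg ~ lipid_class, data = per_sample,
                          FUN = function(x) {
                            c(mean = mean(x),
                              sd = if (length(x) > 1) stats::sd(x) else NA,
                              n = length(x))
                          })
  data.frame(lipid_class = agg$lipid_class,
             mean_nmol_per_mg = agg$nmol_per_mg[, "mean"],
             sd_nmol_per_mg = agg$nmol_per_mg[, "sd"],
             n = as.integer(agg$nmol_per_mg[, "n"]),
             stringsAsFactors = FALSE)
}

#' Fatty-acid mol% from resolved TG compositions
#'
#' Each composition contributes `amount * (count of the FA in the triplet)`
#' mol of that fatty acid; percentages are taken over the total FA mol.
#'
#' @param compositions character vector of composition strings
#'   (`"18:3_22:1_22:1"`).
#' @param amounts species amounts on a molar scale (nmol or nmol/mg), same
#'   length.
#' @return Data frame `fa`, `mol_percent`, sorted by chain; percentages
#'   sum to 100.
#' @examples
#' fa_mol_percent(c("18:3_22:1_22:1", "18:1_18:3_22:1"), c(1, 1))
#' @export
fa_mol_percent <- function(compositions, amounts) {
  stopifnot(length(compositions) == length(amounts))
  mol <- new.env(parent = emptyenv())
  for (i in seq_along(compositions)) {
    fas <- strsplit(compositions[i], "_")[[1]]
    for (fa in fas) {
      mol[[fa]] <- (mol[[fa]] %||% 0) + amounts[i]
    }
  }
  fas <- ls(mol)
  m <- vapply(fas, function(f) mol[[f]], numeric(1))
  key <- vapply(lapply(fas, parse_fa),
                function(f) f$carbons * 100 + f$double_bonds, numeric(1))
  ord <- order(key)
  data.frame(fa = fas[ord], mol_percent = 100 * m[ord] / sum(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a statistics-ready feature table
#'
#' Samples in rows, one column per species feature, with a group label
#' column -- the layout consumed by downstream multivariate statistics
#' tools.
#'
#' @param quant tidy data frame from [quantify_areas()].
#' @param groups named character vector mapping sample id to group label.
#' @param path optional CSV output path.
#' @return The wide data frame (invisibly if written to `path`).
#' @export
export_stats_table <- function(quant, groups = NULL, path = NULL) {
  species <- sort(unique(quant$species))
  samples <- unique(quant$sample)
  wide <- data.frame(Sample = samples, stringsAsFactors = FALSE)
  wide$Label <- if (is.null(groups)) "all" else unname(groups[samples])
  for (sp in species) {
    v <- vapply(samples, function(smp) {
      x <- quant$nmol_per_mg[quant$sample == smp & quant$species == sp]
      if (length(x) == 0) 0 else sum(x)
    }, numeric(1))
    wide[[sp]] <- unname(v)
  }
  if (!is.null(path)) {
    utils::write.csv(wide, path, row.names = FALSE, quote = TRUE)
    return(invisible(wide))
  }
  wide
}
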
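test_that("normalization arithmetic and error contract", {
  expect_equal(normalize_species(1e5, 1e5, 1, 1), 1.0)
  expect_equal(normalize_species(2e5, 1e5, 1, 10), 0.2)
  expect_equal(normalize_species(2e5, 1e5, 0.1, 10), 0.02)
  expect_error(normalize_species(1e5, 0, 1, 10, context = "sample a, class TG"),
               "sample a, class TG")
  expect_error(normalize_species(1e5, 1e5, 1, 0), "tissue mass")
})

test_that("normalization is linear in area and inverse-linear in mass", {
  set.seed(5)
  for (i in 1:20) {
    area <- runif(1, 1e3, 1e6)
    is_area <- runif(1, 1e3, 1e6)
    nmol <- runif(1, 0.1, 5)
    mg <- runif(1, 1, 50)
    k <- runif(1, 0.5, 4)
    expect_equal(normalize_species(k * area, is_area, nmol, mg),
                 k * normalize_species(area, is_area, nmol, mg))
    expect_equal(normalize_species(area, is_area, nmol, k * mg),
                 normalize_species(area, is_area, nmol, mg) / k)
  }
})

test_that("quantification recovers simulated ground truth", {
  mk <- function(nmol, seed) {
    synthetic_sample(data.frame(
      name = c("PC 34:2 (18:2_16:0)", "PC 36:4 (18:2_18:2)",
               "TG 54:3 (18:1_18:1_18:1)"),
      nmol = nmol, stringsAsFactors = FALSE),
      tissue_mg = 10,
      is_spikes = c("PC 33:1 (16:1_17:0)[D5]" = 0.5,
                    "TG 49:1 (16:0_17:1_16:0)[D5]" = 0.5), seed = seed)
  }
  samples <- list(r1 = mk(c(2, 1, 30), 1), r2 = mk(c(2.4, 0.8, 27), 2))
  at <- simulate_area_table(samples, noise = NULL)
  q <- quantify_areas(at, tissue_mg = 10)
  expect_equal(q$nmol_per_mg[q$sample == "r1" &
                               q$species == "PC 34:2 (18:2_16:0)"], 0.2)
  expect_equal(q$nmol_per_mg[q$sample == "r2" &
                               q$species == "TG 54:3 (18:1_18:1_18:1)"], 2.7)
  # internal-standard rows are consumed, not reported
  expect_false(any(grepl("\\[D5\\]", q$species)))
  # with default noise, recovery stays within a few noise SDs
  at_n <- simulate_area_table(samples, seed = 3)
  q_n <- quantify_areas(at_n, tissue_mg = 10)
  expect_equal(q_n$nmol_per_mg, q$nmol_per_mg, tolerance = 3 * 0.02 * 2)
})

test_that("missing internal standards are reported by class", {
  at <- data.frame(species = "PC 34:2 (18:2_16:0)", s1 = 100,
                   stringsAsFactors = FALSE)
  expect_error(quantify_areas(at), "class PC")
})

test_that("class totals aggregate species then replicates", {
  q <- data.frame(sample = rep(c("a", "b"), each = 2),
                  lipid_class = "PC",
                  species = rep(c("PC 34:2 (18:2_16:0)",
                                  "PC 36:4 (18:2_18:2)"), 2),
                  nmol_per_mg = c(1, 2, 2, 3), stringsAsFactors = FALSE)
  ct <- class_totals(q)
  totals <- c(3, 5)  # per-sample sums
  expect_equal(ct$mean_nmol_per_mg, mean(totals))
  # two-pass oracle for the sample SD
  expect_equal(ct$sd_nmol_per_mg,
               sqrt(sum((totals - mean(totals))^2) / (length(totals) - 1)))
  # single replicate: SD is undefined and reported empty
  ct1 <- class_totals(q[q$sample == "a", ])
  expect_true(is.na(ct1$sd_nmol_per_mg))
  # equal replicates: SD zero
  q$nmol_per_mg <- c(1, 2, 1, 2)
  expect_equal(class_totals(q)$sd_nmol_per_mg, 0)
})

test_that("FA mol% weights each chain by its multiplicity", {
  expect_equal(fa_mol_percent("18:1_18:1_18:1", 5)$mol_percent, 100)
  eq <- fa_mol_percent("18:2_22:1_24:1", 1)
  expect_equal(eq$mol_percent, rep(100 / 3, 3))
  # hand count: 6 FA mol total, 22:1 appears 3x, 18:3 2x, 18:1 1x
  mix <- fa_mol_percent(c("18:3_22:1_22:1", "18:1_18:3_22:1"), c(1, 1))
  expect_equal(mix$mol_percent[mix$fa == "22:1"], 50)
  expect_equal(mix$mol_percent[mix$fa == "18:3"], 100 / 3)
  expect_equal(mix$mol_percent[mix$fa == "18:1"], 100 / 6)
  expect_equal(sum(mix$mol_percent), 100, tolerance = 1e-9)
})

test_that("stats export round-trips at full precision in canonical order", {
  q <- data.frame(sample = rep(c("a", "b"), each = 2),
                  lipid_class = "PC",
                  species = rep(c("PC 36:4 (18:2_18:2)",
                                  "PC 34:2 (18:2_16:0)"), 2),
                  nmol_per_mg = c(1.23456789, 2, 3, 4),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  w <- export_stats_table(q, groups = c(a = "dev", b = "mat"), path = path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(names(back), names(w))
  # columns in canonical (sorted) species order
  expect_equal(names(w)[-(1:2)], sort(unique(q$species)))
  expect_equal(back[["PC 36:4 (18:2_18:2)"]], c(1.23456789, 3))
  expect_equal(back$Label, c("dev", "mat"))
})
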
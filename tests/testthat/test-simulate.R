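test_that("retention follows equivalent-carbon-number ordering", {
  m <- retention_model("TG")
  # more double bonds elute earlier at equal carbons
  expect_lt(predict_rt("TG 54:5 (18:1_18:2_18:2)", m),
            predict_rt("TG 54:3 (18:1_18:1_18:1)", m))
  # more carbons elute later at equal double bonds
  expect_gt(predict_rt("TG 60:3 (20:1_20:1_20:1)", m),
            predict_rt("TG 54:3 (18:1_18:1_18:1)", m))
  # identical species, identical RT
  expect_identical(predict_rt("TG 54:3 (18:1_18:1_18:1)", m),
                   predict_rt("TG 54:3 (18:1_18:1_18:1)", m))
  # calibration anchors reproduce the observed standards RTs
  expect_equal(predict_rt("TG 54:9 (18:3_18:3_18:3)", m), 9.7,
               tolerance = 0.02)
  expect_equal(predict_rt("TG 72:3 (24:1_24:1_24:1)", m), 26.7,
               tolerance = 0.02)
  # predictions are clipped to the class elution window
  expect_equal(predict_rt(lipid_species("TG", total_c = 42, total_db = 6),
                          m), 9.7)
})

test_that("random elution-order property holds across the class model", {
  set.seed(3)
  m <- retention_model("DG")
  for (i in 1:20) {
    c1 <- sample(seq(28, 44, 2), 1)
    db <- sample(0:4, 1)
    sp1 <- lipid_species("DG", total_c = c1, total_db = db)
    sp2 <- lipid_species("DG", total_c = c1 + 2, total_db = db)
    sp3 <- lipid_species("DG", total_c = c1, total_db = db + 1)
    r1 <- predict_rt(sp1, m); r2 <- predict_rt(sp2, m); r3 <- predict_rt(sp3, m)
    if (r1 > m$window[1] && r1 < m$window[2] &&
        r2 > m$window[1] && r2 < m$window[2]) expect_gt(r2, r1)
    if (r1 > m$window[1] && r1 < m$window[2] &&
        r3 > m$window[1] && r3 < m$window[2]) expect_lt(r3, r1)
  }
})

test_that("simulated traces are bitwise-deterministic under a fixed seed", {
  smp <- random_tg_sample(n_species = 4, seed = 9)
  x1 <- simulate_xics(smp)
  x2 <- simulate_xics(smp)
  expect_identical(lapply(x1, `[[`, "intensity"),
                   lapply(x2, `[[`, "intensity"))
  x3 <- simulate_xics(smp, seed = 10)
  expect_false(identical(lapply(x1, `[[`, "intensity"),
                         lapply(x3, `[[`, "intensity")))
})

test_that("channel height is proportional to FA multiplicity at zero noise", {
  smp <- synthetic_sample(data.frame(name = "TG 62:5 (18:3_22:1_22:1)",
                                     nmol = 1), is_spikes = c())
  xics <- simulate_xics(smp, noise = NULL)
  h <- sapply(xics, function(tr) max(tr$intensity))
  names(h) <- sapply(xics, function(tr) tr$fa)
  expect_equal(unname(h["22:1"] / h["18:3"]), 2, tolerance = 1e-9)
})

test_that("an empty sample yields flat baseline traces", {
  smp <- synthetic_sample(data.frame(name = character(0),
                                     nmol = numeric(0)),
                          is_spikes = c())
  panel <- build_tg_panel("TG 54:3")
  xics <- suppressWarnings(simulate_xics(smp, panel = panel, noise = NULL,
                                         time_range = c(10, 20)))
  expect_true(all(sapply(xics, function(tr) all(tr$intensity == 0))))
})

test_that("integrated peak area matches the analytic Gaussian integral", {
  smp <- synthetic_sample(data.frame(name = "TG 54:3 (18:1_18:1_18:1)",
                                     nmol = 2), is_spikes = c())
  xics <- simulate_xics(smp, noise = NULL, time_step = 0.005)
  tr <- xics[[1]]
  peak <- detect_peaks(tr)
  analytic <- 2 * 3 * 1e5 * 0.08 * sqrt(2 * pi)
  expect_equal(peak$area, analytic, tolerance = 0.01)
})

test_that("area table carries IS rows, zero-abundance zeros, determinism", {
  s <- synthetic_sample(data.frame(name = c("TG 54:3 (18:1_18:1_18:1)",
                                            "PC 34:2 (18:2_16:0)"),
                                   nmol = c(1, 0)),
                        is_spikes = c("TG 49:1 (16:0_17:1_16:0)[D5]" = 0.5,
                                      "PC 33:1 (16:1_17:0)[D5]" = 0.5))
  at <- simulate_area_table(list(rep1 = s), noise = NULL)
  expect_true(all(c("TG 49:1 (16:0_17:1_16:0)[D5]",
                    "PC 33:1 (16:1_17:0)[D5]") %in% at$species))
  expect_equal(at$rep1[at$species == "PC 34:2 (18:2_16:0)"], 0)
  expect_identical(simulate_area_table(list(rep1 = s), seed = 4),
                   simulate_area_table(list(rep1 = s), seed = 4))
})
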
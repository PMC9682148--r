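test_that("peak detection: flat trace, clean Gaussian, resolved pair", {
  flat <- make_trace(numeric(0), numeric(0))
  expect_equal(nrow(detect_peaks(flat)), 0)

  one <- make_trace(12, 1e5, width = 0.08, step = 0.005)
  p <- detect_peaks(one)
  expect_equal(nrow(p), 1)
  expect_equal(p$rt_apex, 12, tolerance = 0.01)
  expect_equal(p$area, 1e5 * 0.08 * sqrt(2 * pi), tolerance = 0.01)

  two <- make_trace(c(12, 12.5), c(1e5, 5e4), width = 0.08, step = 0.005)
  expect_equal(nrow(detect_peaks(two)), 2)
})

test_that("noise floor suppresses spurious maxima", {
  noisy <- make_trace(12, 5e4, noise_sd = 500, seed = 2)
  p <- detect_peaks(noisy, min_snr = 5)
  expect_equal(nrow(p), 1)
  expect_equal(p$rt_apex, 12, tolerance = 0.03)
})

test_that("co-elution grouping equals the all-pairs clustering oracle", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    rts <- sort(runif(n, 15, 17))
    tol <- runif(1, 0.02, 0.3)
    peaks <- data.frame(transition_id = paste0("t", seq_len(n)),
                        fa = paste0("f", seq_len(n)), rt_apex = rts,
                        height = runif(n, 1, 10), area = 1,
                        rt_lo = rts - 0.1, rt_hi = rts + 0.1,
                        stringsAsFactors = FALSE)
    groups <- group_by_coelution(peaks, rt_tol = tol)
    got <- rep(NA_integer_, n)
    for (g in seq_along(groups)) {
      got[match(groups[[g]]$peaks$rt_apex, rts)] <- g
    }
    want <- oracle_cluster(rts, tol)
    # same partition up to relabelling
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
  }
})

test_that("consensus RT is the height-weighted mean of member apexes", {
  peaks <- data.frame(transition_id = c("a", "b"), fa = c("18:1", "18:2"),
                      rt_apex = c(20.00, 20.04), height = c(3, 1),
                      area = c(1, 1), rt_lo = 0, rt_hi = 0,
                      stringsAsFactors = FALSE)
  g <- group_by_coelution(peaks, rt_tol = 0.05)
  expect_length(g, 1)
  expect_equal(g[[1]]$rt, (20.00 * 3 + 20.04 * 1) / 4)
})

fig2_sample <- function() {
  synthetic_sample(data.frame(
    name = c("TG 58:5 (18:2_18:2_22:1)", "TG 58:5 (18:1_18:3_22:1)",
             "TG 62:5 (18:3_22:1_22:1)", "TG 64:4 (18:2_22:1_24:1)",
             "TG 54:3 (18:1_18:1_18:1)"),
    nmol = c(2, 1, 1.5, 1, 3), stringsAsFactors = FALSE), seed = 7)
}

test_that("isobaric TG 58:5 resolves into its two molecular species", {
  res <- resolve_tg_xics(simulate_xics(fig2_sample(), noise = NULL))
  calls <- res$calls[res$calls$tg_species == "TG 58:5", ]
  expect_equal(sort(calls$composition),
               c("18:1_18:3_22:1", "18:2_18:2_22:1"))
  expect_true(all(calls$confidence == "confirmed"))
  # the shared 22:1 channel is never the quantifier when alternatives exist
  expect_false(any(calls$quantifier_fa == "22:1"))
})

test_that("a 2:1 channel ratio confirms the double-chain composition", {
  res <- resolve_tg_xics(simulate_xics(fig2_sample(), noise = NULL))
  call <- res$calls[res$calls$tg_species == "TG 62:5", ]
  expect_equal(call$composition, "18:3_22:1_22:1")
  expect_equal(call$confidence, "confirmed")
})

test_that("three equal channels give a single confirmed triplet", {
  res <- resolve_tg_xics(simulate_xics(fig2_sample(), noise = NULL))
  call <- res$calls[res$calls$tg_species == "TG 64:4", ]
  expect_equal(nrow(call), 1)
  expect_equal(call$composition, "18:2_22:1_24:1")
  expect_equal(call$confidence, "confirmed")
})

test_that("a mono-acid TG is quantified with divisor three", {
  res <- resolve_tg_xics(simulate_xics(fig2_sample(), noise = NULL))
  call <- res$calls[res$calls$tg_species == "TG 54:3", ]
  expect_equal(call$composition, "18:1_18:1_18:1")
  expect_equal(call$divisor, 3L)
  expect_equal(call$quantifier_fa, "18:1")
})

test_that("one transition is selected per call; divisor = multiplicity", {
  # a single species with three distinct FAs: exactly one quantifier kept
  smp <- synthetic_sample(data.frame(name = "TG 54:2 (16:0_18:1_20:1)",
                                     nmol = 1), seed = 3)
  res <- resolve_tg_xics(simulate_xics(smp, noise = NULL))
  call <- res$calls[res$calls$tg_species == "TG 54:2", ]
  expect_equal(nrow(call), 1)
  expect_length(call$quantifier_fa, 1)
  expect_equal(call$divisor, 1L)
})

test_that("no double counting: corrected areas conserve the precursor", {
  res <- resolve_tg_xics(simulate_xics(fig2_sample(), noise = NULL))
  calls <- res$calls[res$calls$tg_species == "TG 58:5", ]
  # single-channel-equivalent total of the precursor: all channel areas / 3
  area_unit <- 1e5 * 0.08 * sqrt(2 * pi)
  total_equiv <- (2 + 1) * area_unit  # 2 + 1 nmol of the two species
  expect_lte(sum(calls$area_raw / calls$divisor), total_equiv * 1.02)
  expect_equal(sum(calls$area_raw / calls$divisor), total_equiv,
               tolerance = 0.02)
})

test_that("resolution is deterministic for identical traces", {
  xics <- simulate_xics(fig2_sample())
  r1 <- resolve_tg_xics(xics)
  r2 <- resolve_tg_xics(xics)
  expect_identical(r1$calls, r2$calls)
})

test_that("a group supporting no candidate warns and yields no call", {
  # 18:0-only channel on a precursor whose candidates all need other FAs
  tr <- make_trace(15, 1e5, id = "TG 58:5|loss:18:0", fa = "18:0")
  tr$precursor <- "TG 58:5"
  xics <- structure(list(tr), class = "xic_set")
  expect_warning(res <- resolve_tg_xics(xics), "supports no candidate")
  expect_equal(nrow(res$calls), 0)
})
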
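test_that("enumeration equals the brute-force oracle on random pools", {
  set.seed(11)
  all_fas <- c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "18:3",
               "20:0", "20:1", "20:2", "22:1", "24:1")
  for (i in 1:20) {
    pool <- sample(all_fas, sample(2:8, 1))
    total_c <- sample(seq(40, 70, 2), 1)
    total_db <- sample(0:7, 1)
    expect_identical(pkg_enumerate(total_c, total_db, pool),
                     oracle_enumerate(total_c, total_db, pool),
                     label = sprintf("%d:%d over {%s}", total_c, total_db,
                                     paste(pool, collapse = ",")))
  }
})

test_that("published isobaric examples appear among the candidates", {
  c58 <- pkg_enumerate(58, 5, sapply(default_fa_pool(), format))
  expect_true(all(c("18:2_18:2_22:1", "18:1_18:3_22:1") %in% c58))
  c62 <- pkg_enumerate(62, 5, sapply(default_fa_pool(), format))
  expect_true(all(c("18:3_22:1_22:1", "18:3_20:1_24:1") %in% c62))
  expect_identical(pkg_enumerate(54, 0, "18:0"), "18:0_18:0_18:0")
  expect_length(pkg_enumerate(55, 0, "18:0"), 0)  # empty result is valid
})

test_that("every emitted composition conserves the sum composition", {
  for (cmp in enumerate_tg_compositions(60, 4)) {
    expect_equal(sum(sapply(cmp, function(f) f$carbons)), 60)
    expect_equal(sum(sapply(cmp, function(f) f$double_bonds)), 4)
  }
})

test_that("TG panel has one channel per distinct candidate FA, no dupes", {
  panel <- build_tg_panel("TG 58:5")
  comps <- enumerate_tg_compositions(58, 5)
  distinct_fas <- sort(unique(unlist(lapply(comps, function(cmp) {
    sapply(cmp, format)
  }))))
  expect_setequal(sub("^loss:", "", panel$channel), distinct_fas)
  expect_false(any(duplicated(panel[, c("q1_mz", "q3_mz")])))

  one <- build_tg_panel("TG 54:0", pool = list(parse_fa("18:0")))
  expect_equal(nrow(one), 1)
  expect_equal(one$channel, "loss:18:0")

  p64 <- build_tg_panel("TG 64:4")
  expect_true(all(c("loss:18:2", "loss:22:1", "loss:24:1") %in% p64$channel))
})

test_that("panel building is idempotent and canonically ordered", {
  p1 <- build_tg_panel(c("TG 58:5", "TG 62:5", "TG 64:4"))
  p2 <- build_tg_panel(c("TG 58:5", "TG 62:5", "TG 64:4"))
  expect_identical(p1, p2)
})

test_that("a precursor with no candidate warns and keeps no channels", {
  expect_warning(p <- build_tg_panel("TG 47:0"), "no candidate")
  expect_true(is.na(p$q3_mz))
  expect_equal(p$n_candidates, 0L)
})

test_that("scheduled polar panel centres a 3-minute window on the RT", {
  p <- build_polar_panel("LPE 18:1", rt = c("LPE 18:1" = 7.5))
  expect_equal(p$rt_lo, 6.0)
  expect_equal(p$rt_hi, 9.0)
  expect_equal(p$q1_mz, 478.3)
  # class-level default when no species RT is given
  p2 <- build_polar_panel("PI 34:2 (18:2_16:0)")
  expect_equal(p2$rt_min, 8.5)
  # unscheduled mode carries no windows
  p3 <- build_polar_panel("LPE 18:1", scheduled = FALSE)
  expect_true(is.na(p3$rt_window_s))
})

test_that("polar quantifier defaults to the lower-m/z carboxylate", {
  p <- build_polar_panel("PC 31:1 (14:1_17:0)[D5]")
  expect_equal(p$channel, "carboxylate:14:1")
  expect_equal(p$q3_mz, 225.2)
  p2 <- build_polar_panel("PC 31:1 (14:1_17:0)[D5]",
                          quantifier_fa = c("PC 31:1 (14:1_17:0)[D5]" = "17:0"))
  expect_equal(p2$channel, "carboxylate:17:0")
})

test_that("pool validation rejects empty and duplicated pools", {
  expect_error(enumerate_tg_compositions(54, 0, list()), "non-empty")
  expect_error(enumerate_tg_compositions(54, 0,
                                         lapply(c("18:0", "18:0"), parse_fa)),
               "duplicates")
})
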
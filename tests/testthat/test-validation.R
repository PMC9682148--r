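test_that("calibration fit matches the closed-form normal equations", {
  set.seed(8)
  amount <- 2 * 4^(0:8) / 100  # 9-point serial dilution
  response <- 50 * amount * (1 + rnorm(9, 0, 0.01))
  fit <- fit_calibration(amount, response, noise_sd = 0.05)
  # normal-equations oracle
  sxx <- sum((amount - mean(amount))^2)
  sxy <- sum((amount - mean(amount)) * (response - mean(response)))
  slope <- sxy / sxx
  intercept <- mean(response) - slope * mean(amount)
  r2 <- 1 - sum((response - intercept - slope * amount)^2) /
    sum((response - mean(response))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_gt(fit$r_squared, 0.99)
})

test_that("exact line and degenerate input contracts", {
  fit <- fit_calibration(c(1, 2, 4), c(2, 4, 8))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_calibration(c(1, 2, 4), c(0, 0, 0)), "degenerate")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_calibration(c(0, 1, 2), c(0, 1, 2)), "> 0")
})

test_that("LOQ/LOD ratio is exactly 10/3 for any input", {
  set.seed(12)
  for (i in 1:20) {
    lims <- lod_loq(runif(1, 0, 100), runif(1, 0.01, 50))
    expect_equal(lims[["loq"]] / lims[["lod"]], 10 / 3, tolerance = 1e-12)
  }
  expect_equal(lod_loq(0, 1), c(lod = 0, loq = 0))
  expect_equal(lod_loq(3, 1), c(lod = 9, loq = 30))
  expect_error(lod_loq(1, 0), "slope")
  expect_error(lod_loq(-1, 1), "noise")
})

test_that("linear range is bounded by LOQ and the 15% deviation rule", {
  amount <- c(0.5, 1, 2, 4, 8, 16, 32)
  response <- 2 * amount
  response[7] <- 2 * 32 * 0.7  # saturating top point, 30% low
  fit <- fit_calibration(amount, response, noise_sd = 0.6)
  # the saturated top point is excluded from the linear range and the fit
  expect_equal(fit$linear_range[2], 16)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  # loq = 10*0.6/2 = 3; lower bound is the lowest point at or above it
  expect_equal(fit$loq, 3)
  expect_equal(fit$linear_range[1], 4)
  # an unsaturated series keeps its full span
  fit2 <- fit_calibration(amount, 2 * amount, noise_sd = 0.6)
  expect_equal(fit2$linear_range[2], 32)
})

test_that("recovery efficiency and matrix effect identities", {
  expect_equal(recovery_efficiency(1000, 1000), 100)
  expect_equal(recovery_efficiency(750, 1000), 75)
  expect_equal(matrix_effect(1000, 1000), 0)
  expect_equal(matrix_effect(680, 1000), -32)
  expect_equal(matrix_effect(1100, 1000), 10)
  expect_error(recovery_efficiency(500, 0), "> 0")
  expect_error(matrix_effect(500, 0), "> 0")
})

test_that("replicates aggregate as a ratio of means", {
  set.seed(21)
  before <- runif(5, 700, 800)
  after <- runif(5, 900, 1100)
  alone <- runif(5, 1000, 1200)
  expect_equal(recovery_efficiency(before, after),
               mean(before) / mean(after) * 100, tolerance = 1e-12)
  expect_equal(matrix_effect(after, alone),
               mean(after) / mean(alone) * 100 - 100, tolerance = 1e-12)
  # and differs, in general, from the mean of per-replicate ratios
  expect_false(isTRUE(all.equal(recovery_efficiency(before, after),
                                mean(before / after * 100))))
})

test_that("threshold boundaries are inclusive on the ok side", {
  expect_equal(validation_flags(re = 100, me = -25), "ok")
  expect_equal(validation_flags(re = 100, me = -25.01), "suppressed")
  expect_equal(validation_flags(re = 100, me = 25), "ok")
  expect_equal(validation_flags(re = 100, me = 25.01), "enhanced")
  expect_equal(validation_flags(re = 75, me = 0), "ok")
  expect_equal(validation_flags(re = 74.99, me = 0), "low_recovery")
  expect_equal(validation_flags(re = 50, me = -30), "suppressed;low_recovery")
})

test_that("validation report mirrors the flagging rules", {
  rep <- validation_report(
    species = c("LPI 15:0[D5]", "PG 31:1 (14:1_17:0)[D5]"),
    is_before = list(c(360, 359), c(950, 960)),
    is_after = list(c(1000, 1002), c(1000, 995)),
    is_alone = list(c(1220, 1219), c(1085, 1084)))
  expect_equal(rep$flag[1], "low_recovery")
  expect_equal(rep$flag[2], "ok")
  expect_lt(rep$me_percent[1], 0)
})
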
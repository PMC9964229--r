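test_that("climate generation is seeded, bounded and physically ordered", {
  cl <- gen_climate(9, seed = 1)
  expect_equal(nrow(cl), 9)
  expect_true(all(cl$MIT <= cl$AT & cl$AT <= cl$MAT))
  expect_identical(gen_climate(9, seed = 1), cl)
  expect_false(identical(gen_climate(9, seed = 2), cl))
  expect_error(gen_climate(1), ">= 2")

  # configured subtropical-August mean is recovered at moderate n
  big <- gen_climate(100, seed = 7)
  expect_lt(abs(mean(big$AT) - 27), 1)
})

test_that("climate invariants hold across many seeds", {
  for (s in 1:100) {
    cl <- gen_climate(5, seed = s)
    expect_true(all(cl$MIT <= cl$AT & cl$AT <= cl$MAT))
    expect_true(all(cl$ARH >= 0 & cl$ARH <= 100))
    expect_true(all(cl[, c("AP", "DP", "OP", "SD")] >= 0))
    # generator convention: DP + OP is the monthly total, AP its daily mean
    expect_equal(cl$AP, (cl$DP + cl$OP) / 31, tolerance = 1e-12)
  }
})

test_that("planted response truth matches the analytic sensitivities", {
  cl <- gen_climate(50, seed = 3)
  one <- gen_response(cl, effect_spec(linear = c(MIT = 2), noise_sd = 0))
  expect_equal(unname(one$sensitivity[["MIT"]]), 1)
  expect_equal(sum(one$sensitivity), 1)
  expect_true(all(one$sensitivity[setdiff(names(one$sensitivity),
                                          "MIT")] == 0))

  # linear coefficients (1, 2) on z-scored factors -> weights (1/3, 2/3)
  two <- gen_response(cl, effect_spec(linear = c(SD = 1, ARH = 2),
                                      noise_sd = 0))
  expect_equal(unname(two$sensitivity[["SD"]]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(two$sensitivity[["ARH"]]), 2 / 3, tolerance = 1e-12)

  # zero noise: reproducible by direct evaluation of the spec
  z <- scale(cl$MIT)[, 1] * 2
  expect_equal(one$response, z, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(gen_response(cl, effect_spec(linear = c(XX = 1))),
               "unknown climate factor")
})

test_that("dose-response generator hits 50% scavenging at the true IC50", {
  ser <- gen_dose_response(1.0, hill = 2, concentrations = c(0.5, 1, 2),
                           noise_sd = 0)
  s <- scavenging_pct(ser$sample_absorbances, ser$control_absorbance)
  expect_equal(s[2], 50, tolerance = 1e-12)

  # round trip through the estimator
  full <- gen_dose_response(0.8, hill = 2, noise_sd = 0)
  expect_equal(estimate_ic50(full), 0.8, tolerance = 0.02)

  # steep-slope limit approaches a step around the IC50
  steep <- gen_dose_response(1.0, hill = 50,
                             concentrations = c(0.5, 0.99, 1.01, 2),
                             noise_sd = 0)
  s2 <- scavenging_pct(steep$sample_absorbances, steep$control_absorbance)
  expect_lt(s2[1], 1)
  expect_gt(s2[4], 99)

  expect_error(gen_dose_response(1, concentrations = c(-1, 1)), "positive")
  expect_error(gen_dose_response(-1), "> 0")
})

test_that("OD generator inverts the flavonoid formula exactly", {
  cc <- calibration_curve(10.655, -0.0076)
  spec <- extraction_spec(dilution_factor = 10)
  for (tfc in c(114.5, 200, 345.4)) {
    od <- gen_tfc_od(tfc, cc, spec, noise_sd = 0)
    expect_equal(length(unique(od)), 1L)  # noiseless triplicate identical
    expect_equal(compute_tfc(od, cc, spec)$tfc_mg_g, tfc,
                 tolerance = 1e-10)
  }
  # undiluted extract at high content implies an impossible photometry read
  expect_error(gen_tfc_od(345.4, cc, extraction_spec(dilution_factor = 1)),
               "outside \\[0, 4\\]")
})

test_that("peak-list mass noise is calibrated in ppm", {
  clean <- gen_peak_list("C27H30O16", "[M-H]-", ppm_noise = 0)
  expect_equal(round(clean$mz, 4), 609.1461)
  expect_equal(clean$mz, clean$theoretical_mz)

  noisy <- gen_peak_list(rep("C27H30O16", 1000), "[M-H]-", ppm_noise = 5,
                         seed = 9)
  emp <- (noisy$mz / noisy$theoretical_mz - 1) * 1e6
  expect_lt(abs(sd(emp) - 5), 0.5)
  expect_error(gen_peak_list(character(0)), "non-empty")
})

test_that("the simulated study carries coherent ground truth", {
  st <- simulate_study(n_sites = 9, seed = 4)
  expect_s3_class(st, "synthetic_study")
  expect_true(all(st$truth$tfc >= 120 & st$truth$tfc <= 350))
  expect_true(all(st$truth$ic50 > 0))
  expect_true(all(abs(colSums(st$truth$sensitivities) - 1) < 1e-9))
  expect_equal(dim(st$responses), c(9L, 8L))
  # determinism of the whole bundle
  st2 <- simulate_study(n_sites = 9, seed = 4)
  expect_identical(st$od, st2$od)
  expect_identical(st$dose_response$absorbance, st2$dose_response$absorbance)
})
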
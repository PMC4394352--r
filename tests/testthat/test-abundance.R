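test_that("calibration recovers an exact line", {
  std <- tibble::tibble(mass_pmol = c(0.25, 0.5, 1, 2),
                        signal = 1000 * c(0.25, 0.5, 1, 2))
  curve <- fit_calibration(std)
  expect_equal(curve$slope, 1000, tolerance = 1e-9)
  expect_equal(curve$intercept, 0, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$n_standards, 4)
})

test_that("a saturated top standard is detected and excluded", {
  std <- tibble::tibble(
    mass_pmol = c(0.25, 0.5, 1, 2, 4),
    signal = c(1000 * c(0.25, 0.5, 1, 2), 0.7 * 1000 * 4)  # 30% short
  )
  curve <- fit_calibration(std)
  expect_equal(curve$n_standards, 4)
  expect_equal(curve$excluded$mass_pmol, 4)
  expect_equal(curve$slope, 1000, tolerance = 1e-9)
  expect_equal(curve$linear_range_max, 2000)
})

test_that("degenerate standards are rejected", {
  expect_error(
    fit_calibration(tibble::tibble(mass_pmol = c(1, 2, 4), signal = 0)),
    "zero signal", class = "holophos_input_error"
  )
  expect_error(
    fit_calibration(tibble::tibble(mass_pmol = c(1, 2), signal = c(1, 2))),
    class = "holophos_input_error"
  )
})

test_that("signal converts to mass only inside the linear range", {
  curve <- fit_calibration(
    tibble::tibble(mass_pmol = c(0.25, 0.5, 1), signal = c(250, 500, 1000))
  )
  expect_equal(lane_to_moles(500, curve), 0.5, tolerance = 1e-9)
  # boundary accepted
  expect_equal(lane_to_moles(curve$linear_range_max, curve), 1,
               tolerance = 1e-9)
  expect_error(lane_to_moles(2 * curve$linear_range_max, curve),
               class = "holophos_saturation_error")
})

test_that("packed-cell accounting follows the volume model", {
  model <- cell_volume_model()
  expect_equal(model$cytosol_fraction, 0.30)
  # 5 ul packed cells -> 1.5 ul cytosol
  expect_equal(concentration_from_moles(0.5, 5), 0.5 / 1.5,
               tolerance = 1e-12)
  expect_identical(concentration_from_moles(0, 5), 0)
  # scale invariance
  expect_equal(concentration_from_moles(1, 10),
               concentration_from_moles(2, 20), tolerance = 1e-12)
  expect_error(concentration_from_moles(0.5, 0),
               class = "holophos_input_error")
  # mass route: 1.005 g/ml buoyant density
  expect_equal(packed_volume_from_mass(5.025), 5, tolerance = 1e-12)
})

test_that("molecule counts convert to molar concentration", {
  expect_equal(molecules_to_concentration(6.02214076e5, 1000, 1), 1,
               tolerance = 1e-12)
  expect_identical(molecules_to_concentration(0, 60, 0.5), 0)
  expect_error(molecules_to_concentration(1e4, 0, 0.5),
               class = "holophos_input_error")
  expect_error(molecules_to_concentration(1e4, 60, 1.5),
               class = "holophos_input_error")
})

test_that("abundance estimates are invariant to fluorescence units", {
  cfg <- sim_config(noise_cv = 0.03, seed = 9)
  blot <- simulate_blot(cfg)
  est1 <- estimate_abundance(blot$lysate, fit_calibration(blot$standards))

  scale_f <- 17.3
  std2 <- dplyr::mutate(blot$standards, signal = scale_f * .data$signal)
  lys2 <- dplyr::mutate(blot$lysate, signal = scale_f * .data$signal)
  est2 <- estimate_abundance(lys2, fit_calibration(std2))
  expect_equal(est2$concentration_uM, est1$concentration_uM,
               tolerance = 1e-10)
})

test_that("lysate lanes above the linear range are excluded per sample", {
  cfg <- sim_config(noise_cv = 0, blot_saturation = 1500,
                    lysate_pcv_ul = c(0.5, 1, 2, 4), seed = 5)
  blot <- simulate_blot(cfg)
  curve <- fit_calibration(blot$standards)
  est <- estimate_abundance(blot$lysate, curve)
  expect_true(all(est$n_saturated >= 1))
  expect_equal(est$concentration_uM, rep(cfg$lysate_conc_uM, 2),
               tolerance = 1e-9)
})
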
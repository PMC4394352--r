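make_lanes <- function(ip, id, total = 2, time = 5) {
  tibble::tibble(
    condition_label = "c", replicate_id = "r1",
    time_min = time, substrate_total_uM = total,
    enzyme_uM = 0.026, effector_uM = 0,
    intensity_phospho = ip, intensity_dephospho = id
  )
}

test_that("fraction dephosphorylated is the ratiometric band split", {
  expect_identical(fraction_dephosphorylated(0, 5), 1.0)
  expect_identical(fraction_dephosphorylated(7, 7), 0.5)
  expect_identical(fraction_dephosphorylated(3, 1), 0.25)
  expect_equal(fraction_dephosphorylated(c(0, 7, 3), c(5, 7, 1)),
               c(1, 0.5, 0.25))
})

test_that("lanes partition total substrate exactly between species", {
  q <- quantify_lanes(make_lanes(c(7, 2.8, 3), c(7, 0, 1),
                                 total = c(2, 2.8, 1.7)))
  expect_equal(q$substrate_uM, c(1.0, 2.8, 1.275))
  expect_equal(q$product_uM, c(1.0, 0, 0.425))
  # conservation holds exactly for every lane
  expect_identical(q$substrate_uM + q$product_uM, q$substrate_total_uM)
})

test_that("quantification is invariant to per-lane loading factors", {
  withr::with_seed(11, {
    for (i in 1:20) {
      ip <- stats::runif(1, 0, 100)
      id <- stats::runif(1, 0.1, 100)
      base <- quantify_lanes(make_lanes(ip, id))
      # exactly representable factors scale both bands without rounding
      # the inputs: the ratio is then bit-identical
      c_exact <- 2^sample(-10:10, 1)
      exact <- quantify_lanes(make_lanes(c_exact * ip, c_exact * id))
      expect_identical(exact$fraction, base$fraction)
      expect_identical(exact$substrate_uM, base$substrate_uM)
      expect_identical(exact$product_uM, base$product_uM)
      # an arbitrary real factor perturbs the recorded intensities by up
      # to half an ulp each; the ratio agrees to rounding error
      c_f <- stats::runif(1, 1e-3, 1e3)
      scaled <- quantify_lanes(make_lanes(c_f * ip, c_f * id))
      expect_equal(scaled$fraction, base$fraction, tolerance = 1e-14)
    }
  })
})

test_that("degenerate lanes are rejected with their identifier", {
  expect_error(quantify_lanes(make_lanes(0, 0, time = 12)),
               "zero total intensity.*c/r1/t=12",
               class = "holophos_input_error")
  expect_error(quantify_lanes(make_lanes(-1, 5)),
               "negative band intensity",
               class = "holophos_input_error")
  expect_error(quantify_lanes(dplyr::select(make_lanes(1, 1),
                                            -"intensity_phospho")),
               "intensity_phospho", class = "holophos_schema_error")
})

test_that("the weak-lane floor excludes rather than errors", {
  lanes <- dplyr::bind_rows(make_lanes(100, 100), make_lanes(1, 1))
  q <- quantify_lanes(lanes, min_total_intensity = 10)
  expect_equal(nrow(q), 1)
  expect_equal(nrow(attr(q, "excluded")), 1)
  # disabled by default
  expect_equal(nrow(quantify_lanes(lanes)), 2)
})
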
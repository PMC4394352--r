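exp_course <- function(k, s0 = 2, times = c(3, 5, 12, 25)) {
  tibble::tibble(time_min = times, substrate_uM = s0 * exp(-k * times))
}

test_that("log decay transform matches hand arithmetic", {
  tc <- tibble::tibble(time_min = c(0, 5, 10),
                       substrate_uM = c(2, 1, 2 * exp(-0.5)))
  s <- log_decay_series(tc, s0 = 2)
  expect_identical(s$log_ratio[1], 0)
  expect_equal(s$log_ratio[2], log(2), tolerance = 1e-12)
  expect_equal(s$log_ratio[3], 0.5, tolerance = 1e-12)
  # base-10 reporting view divides by ln(10)
  s10 <- log_decay_series(tc, s0 = 2, base10 = TRUE)
  expect_equal(s10$log_ratio, s$log_ratio / log(10))
})

test_that("log decay rejects non-positive substrate and flags St > S0", {
  expect_error(
    log_decay_series(tibble::tibble(time_min = c(3, 5),
                                    substrate_uM = c(1, 0)), s0 = 2),
    "St > 0", class = "holophos_input_error"
  )
  expect_warning(
    s <- log_decay_series(tibble::tibble(time_min = c(3, 5),
                                         substrate_uM = c(2.5, 1)),
                          s0 = 2),
    class = "holophos_exceeds_s0_warning"
  )
  # negative transformed value retained, not dropped
  expect_lt(s$log_ratio[1], 0)
  expect_true(s$exceeds_s0[1])
})

test_that("first-order fit recovers the rate constant exactly on noiseless data", {
  fit <- fit_first_order(exp_course(0.1), s0 = 2)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$stderr, 0, tolerance = 1e-14)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$dof, 3)  # through-origin: n - 1
  expect_equal(fit$n_points, 4)

  flat <- fit_first_order(
    tibble::tibble(time_min = c(3, 5, 12), substrate_uM = c(2, 2, 2)),
    s0 = 2
  )
  expect_equal(flat$slope, 0)

  free <- fit_first_order(exp_course(0.1), s0 = 2, intercept = "free")
  expect_equal(free$slope, 0.1, tolerance = 1e-12)
  expect_equal(free$dof, 2)  # free intercept: n - 2
})

test_that("degenerate time courses are rejected", {
  expect_error(fit_first_order(exp_course(0.1, times = 5), s0 = 2),
               class = "holophos_input_error")
  expect_error(
    fit_first_order(tibble::tibble(time_min = c(5, 5),
                                   substrate_uM = c(1.5, 1.4)), s0 = 2),
    class = "holophos_input_error"
  )
})

test_that("initial velocity follows the integrated rate equation", {
  expect_identical(initial_velocity(2, 2, 5, 0.025), 0)
  expect_equal(
    suppressWarnings(initial_velocity(2, 2 * exp(-0.5), 5, 0.025)),
    8.00, tolerance = 1e-12
  )
  # dt-independence on exact first-order data, to machine precision
  k <- 0.02
  vi3 <- initial_velocity(2, 2 * exp(-k * 3), 3, 0.025)
  vi25 <- suppressWarnings(initial_velocity(2, 2 * exp(-k * 25), 25, 0.025))
  expect_equal(vi3, vi25, tolerance = 1e-13)
  expect_equal(vi3, k * 2 / 0.025, tolerance = 1e-13)
})

test_that("the depletion flag fires iff depletion exceeds 25%", {
  expect_silent(initial_velocity(2, 2 * 0.75, 5, 0.025))       # exactly 25%
  expect_warning(initial_velocity(2, 2 * 0.749, 5, 0.025),
                 class = "holophos_depletion_warning")
})

test_that("negative velocities are reported with a warning, not clamped", {
  expect_warning(vi <- initial_velocity(2, 2.2, 5, 0.025),
                 class = "holophos_negative_velocity_warning")
  expect_lt(vi, 0)
  expect_error(initial_velocity(2, 0, 5, 0.025),
               class = "holophos_input_error")
  expect_error(initial_velocity(-1, 1, 5, 0.025),
               class = "holophos_input_error")
})

test_that("velocity vs substrate slope reflects the specificity constant", {
  exact <- tibble::tibble(s0_uM = c(0.5, 1, 2, 3),
                          vi = 0.8 * c(0.5, 1, 2, 3))
  fit <- velocity_vs_substrate(exact)
  expect_equal(fit$slope, 0.800, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # on first-order data the slope equals k / [ENZ]
  k <- 0.02; enz <- 0.005
  pts <- tibble::tibble(
    s0_uM = c(0.5, 1, 2, 3),
    vi = initial_velocity(c(0.5, 1, 2, 3),
                          c(0.5, 1, 2, 3) * exp(-k * 5), 5, enz)
  )
  expect_equal(velocity_vs_substrate(pts)$slope, k / enz,
               tolerance = 1e-12)

  expect_error(
    velocity_vs_substrate(tibble::tibble(s0_uM = c(1, 1), vi = c(1, 2))),
    class = "holophos_input_error"
  )
})

test_that("decay, velocity and slope estimates are mutually consistent", {
  # on noiseless exponentials, slope ratios equal rate-constant ratios
  k1 <- 0.03; k2 <- 0.012; enz <- 0.026
  f1 <- fit_first_order(exp_course(k1), s0 = 2)
  f2 <- fit_first_order(exp_course(k2), s0 = 2)
  expect_equal(f1$slope / f2$slope, k1 / k2, tolerance = 1e-10)

  vv <- function(k) {
    s0 <- c(0.5, 1, 2, 3)
    velocity_vs_substrate(
      tibble::tibble(s0_uM = s0,
                     vi = initial_velocity(s0, s0 * exp(-k * 3), 3, enz))
    )$slope
  }
  expect_equal(vv(k1) / vv(k2), k1 / k2, tolerance = 1e-10)
})

test_that("sub-Km first-order approximation error shrinks with S0/Km", {
  # oracle: numerically integrated Michaelis-Menten course
  kcat <- 10; km <- 40; enz <- 0.026
  err_at <- function(s0) {
    tc <- mm_timecourse(kcat, km, enz, s0, times = c(3, 5, 12, 25))
    slope <- fit_first_order(tc, s0 = s0)$slope
    abs(slope - kcat * enz / km) / (kcat * enz / km)
  }
  e_small <- err_at(0.05 * km)
  e_large <- err_at(0.20 * km)
  expect_lt(e_small, e_large)
  expect_lt(e_large, 0.20)

  # saturation guard: Km comparable to S0 makes the through-origin
  # velocity slope underestimate kcat*E/Km (documented, not corrected)
  s0 <- c(0.5, 1, 2, 3); km_sat <- 2 * max(s0)
  vi <- purrr::map_dbl(s0, function(s) {
    tc <- mm_timecourse(kcat, km_sat, enz, s, times = 5)
    initial_velocity(s, tc$substrate_uM, 5, enz)
  })
  slope <- velocity_vs_substrate(tibble::tibble(s0_uM = s0, vi = vi))$slope
  expect_lt(slope, kcat / km_sat)  # underestimates the sub-Km limit k/[ENZ]
})

test_that("per-condition decay fitting covers a grouped lane table", {
  cfg <- sim_config(k = 0.05, noise_cv = 0, loading_cv = 0, seed = 2)
  rates <- fit_decay_rates(quantify_lanes(simulate_timecourse(cfg)))
  expect_equal(nrow(rates), length(cfg$s0_uM))
  expect_equal(rates$k_per_min, rep(0.05, 4), tolerance = 1e-10)
  expect_true(all(rates$r.squared > 1 - 1e-12))
})
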
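# Seeded generators with the statistical structure the assays produce:
# exponential substrate decay read out as band-intensity pairs with
# multiplicative lane-loading and band-measurement noise, hyperbolic
# velocity activation by G-actin with an optional high-dose decline, and
# a linear-then-saturating immunoblot calibration.
#
# Every generator is a pure function of (config, seed): the same config
# yields byte-identical tables.

#' Simulation configuration
#'
#' Defaults mirror the assay designs the package analyses: time points
#' 3/5/12/25 min; substrate starting concentrations spanning the sub-Km
#' range; tens-of-nanomolar enzyme; lognormal multiplicative noise on
#' band intensities with a per-lane loading factor shared by both bands
#' (so ratiometric quantification is exercised meaningfully); a
#' sub-100-nM EC50 for G-actin activation; a linear immunoblot response
#' with an optional saturation ceiling.
#'
#' @param k First-order rate constant, per minute.
#' @param s0_uM Starting substrate concentrations (µM).
#' @param enzyme_uM Enzyme concentration (µM).
#' @param effector_uM Effector (G-actin) concentration recorded in the
#'   lane table (µM).
#' @param times_min Sampling times (minutes, strictly increasing).
#' @param intensity_scale Arbitrary-unit scale of a fully loaded lane.
#' @param loading_cv Lognormal sigma of the per-lane loading factor.
#' @param noise_cv Lognormal sigma of per-band measurement noise.
#' @param condition_label,replicate_id Metadata written into the tables.
#' @param doses_uM G-actin dose grid (µM, includes 0).
#' @param dr_v0,dr_vmax,dr_ec50 Dose-response truth: baseline and
#'   maximal velocity (per min) and EC50 (µM).
#' @param dr_decline_onset,dr_decline_rate Optional high-dose decline:
#'   above the onset dose (µM) velocities are attenuated by
#'   `1 - dr_decline_rate * (dose - onset)` (floored at 0); `NULL` onset
#'   disables the decline.
#' @param blot_slope,blot_intercept Standard-curve truth (signal per
#'   pmol; background signal).
#' @param blot_saturation Signal ceiling (`NULL`: no saturation).
#' @param standards_pmol Standard loadings (pmol).
#' @param lysate_conc_uM True cytosolic concentration of the simulated
#'   lysate (µM).
#' @param lysate_pcv_ul Packed cell volumes loaded per lysate lane (µl).
#' @param n_samples Number of biological lysate samples.
#' @param seed Integer seed; generators are pure in (config, seed).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(k = 0.1,
                       s0_uM = c(0.5, 1, 2, 3),
                       enzyme_uM = 0.026,
                       effector_uM = 0,
                       times_min = c(3, 5, 12, 25),
                       intensity_scale = 1e4,
                       loading_cv = 0.1,
                       noise_cv = 0.05,
                       condition_label = "sim",
                       replicate_id = "r1",
                       doses_uM = c(0, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8,
                                    1.5, 3),
                       dr_v0 = 1,
                       dr_vmax = 10,
                       dr_ec50 = 0.08,
                       dr_decline_onset = NULL,
                       dr_decline_rate = 0.2,
                       blot_slope = 1000,
                       blot_intercept = 50,
                       blot_saturation = NULL,
                       standards_pmol = c(0.125, 0.25, 0.5, 1, 2, 4),
                       lysate_conc_uM = 1.13,
                       lysate_pcv_ul = c(0.25, 0.5, 1, 2),
                       n_samples = 2,
                       seed = 1L) {
  check_positive(k, "k", strict = FALSE)
  check_positive(s0_uM, "s0_uM")
  check_positive(enzyme_uM, "enzyme_uM")
  check_positive(effector_uM, "effector_uM", strict = FALSE)
  check_positive(times_min, "times_min")
  if (is.unsorted(times_min, strictly = TRUE)) {
    abort("times_min must be strictly increasing",
          class = "holophos_input_error")
  }
  check_positive(intensity_scale, "intensity_scale")
  check_positive(loading_cv, "loading_cv", strict = FALSE)
  check_positive(noise_cv, "noise_cv", strict = FALSE)
  check_positive(doses_uM, "doses_uM", strict = FALSE)
  check_positive(dr_ec50, "dr_ec50")
  check_positive(blot_slope, "blot_slope")
  check_positive(standards_pmol, "standards_pmol")
  check_positive(lysate_conc_uM, "lysate_conc_uM")
  check_positive(lysate_pcv_ul, "lysate_pcv_ul")
  structure(
    list(
      k = k, s0_uM = s0_uM, enzyme_uM = enzyme_uM,
      effector_uM = effector_uM, times_min = times_min,
      intensity_scale = intensity_scale, loading_cv = loading_cv,
      noise_cv = noise_cv, condition_label = condition_label,
      replicate_id = replicate_id, doses_uM = doses_uM, dr_v0 = dr_v0,
      dr_vmax = dr_vmax, dr_ec50 = dr_ec50,
      dr_decline_onset = dr_decline_onset,
      dr_decline_rate = dr_decline_rate, blot_slope = blot_slope,
      blot_intercept = blot_intercept, blot_saturation = blot_saturation,
      standards_pmol = standards_pmol, lysate_conc_uM = lysate_conc_uM,
      lysate_pcv_ul = lysate_pcv_ul, n_samples = n_samples,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

lognoise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else rlnorm(n, meanlog = 0, sdlog = sigma)
}

#' Simulate a dephosphorylation time course as a lane table
#'
#' Substrate decays as `S(t) = S0 * exp(-k t)`; each lane's band pair is
#' the concentration-proportional split of `intensity_scale`, multiplied
#' by a shared lognormal loading factor and independent per-band
#' lognormal measurement noise. A t = 0 reference lane is included for
#' every starting concentration.
#'
#' @param cfg A [sim_config()].
#' @return A tibble in the [lane_schema()] layout.
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(
      substrate_total_uM = cfg$s0_uM,
      time_min = c(0, cfg$times_min)
    )
    st <- grid$substrate_total_uM * exp(-cfg$k * grid$time_min)
    frac_p <- st / grid$substrate_total_uM
    n <- nrow(grid)
    loading <- lognoise(n, cfg$loading_cv)
    tibble::tibble(
      condition_label = cfg$condition_label,
      replicate_id = cfg$replicate_id,
      time_min = grid$time_min,
      substrate_total_uM = grid$substrate_total_uM,
      enzyme_uM = cfg$enzyme_uM,
      effector_uM = cfg$effector_uM,
      intensity_phospho = cfg$intensity_scale * loading * frac_p *
        lognoise(n, cfg$noise_cv),
      intensity_dephospho = cfg$intensity_scale * loading * (1 - frac_p) *
        lognoise(n, cfg$noise_cv)
    )
  })
}

#' Simulate a G-actin dose-response table
#'
#' Velocities follow the hyperbola
#' `v0 + (vmax - v0) * A / (EC50 + A)`, optionally attenuated above a
#' decline-onset dose, with multiplicative lognormal noise.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `dose_uM`, `velocity`, `condition_label`.
#' @export
simulate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    a <- cfg$doses_uM
    v <- cfg$dr_v0 + (cfg$dr_vmax - cfg$dr_v0) * a / (cfg$dr_ec50 + a)
    if (!is.null(cfg$dr_decline_onset)) {
      over <- a > cfg$dr_decline_onset
      v[over] <- v[over] *
        pmax(0, 1 - cfg$dr_decline_rate * (a[over] - cfg$dr_decline_onset))
    }
    tibble::tibble(
      dose_uM = a,
      velocity = v * lognoise(length(a), cfg$noise_cv),
      condition_label = cfg$condition_label
    )
  })
}

#' Simulate immunoblot standards and lysate tables
#'
#' Standards follow `signal = intercept + slope * mass`, clipped at the
#' saturation ceiling when one is set; lysate lanes carry the mass
#' implied by the true cytosolic concentration and each lane's packed
#' cell volume (cytosol is 30% of packed volume under the default
#' [cell_volume_model()]). Both signals get multiplicative lognormal
#' noise.
#'
#' @param cfg A [sim_config()].
#' @param model A [cell_volume_model()] used to derive the loaded
#'   cytosolic volumes.
#' @return List of two tibbles: `standards` (`mass_pmol`, `signal`) and
#'   `lysate` (`sample_id`, `packed_cell_volume_ul`, `signal`).
#' @export
simulate_blot <- function(cfg, model = cell_volume_model()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    clip <- function(x) {
      if (is.null(cfg$blot_saturation)) x else pmin(x, cfg$blot_saturation)
    }
    std_signal <- clip(cfg$blot_intercept +
                         cfg$blot_slope * cfg$standards_pmol) *
      lognoise(length(cfg$standards_pmol), cfg$noise_cv)
    standards <- tibble::tibble(
      mass_pmol = cfg$standards_pmol,
      signal = std_signal
    )
    lys <- tidyr::expand_grid(
      sample_id = paste0("s", seq_len(cfg$n_samples)),
      packed_cell_volume_ul = cfg$lysate_pcv_ul
    )
    mass <- cfg$lysate_conc_uM * lys$packed_cell_volume_ul *
      model$cytosol_fraction
    lysate <- dplyr::mutate(
      lys,
      signal = clip(cfg$blot_intercept + cfg$blot_slope * mass) *
        lognoise(nrow(lys), cfg$noise_cv)
    )
    list(standards = standards, lysate = lysate)
  })
}
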
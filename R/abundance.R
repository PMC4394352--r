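# Cellular substrate concentration from quantitative immunoblots.
#
# A standard curve of recombinant protein (mass in pmol vs fluorescent
# signal) calibrates lysate lanes; signal converts to mass only inside
# the curve's linear range (fluorescent detection saturates). Mass over
# the cytosolic volume of the loaded packed cells gives the cytosolic
# concentration. pmol / ul is exactly uM, so no unit constants appear.

#' Cell-volume model for packed-cell-volume accounting
#'
#' Defaults: buoyant density 1.005 g/ml converts packed cell mass to
#' volume; 60% of the packed cell volume is intracellular, of which half
#' is cytosol (the rest nucleus and organelles), i.e. the cytosol is 30%
#' of the packed volume.
#'
#' @param buoyant_density g/ml (> 0).
#' @param intracellular_fraction Fraction of packed volume that is
#'   intracellular, in (0, 1].
#' @param cytosol_of_intracellular Fraction of intracellular volume that
#'   is cytosol, in (0, 1].
#' @return A `cell_volume_model` list; its `cytosol_fraction` element is
#'   the product of the two fractions.
#' @export
cell_volume_model <- function(buoyant_density = 1.005,
                              intracellular_fraction = 0.60,
                              cytosol_of_intracellular = 0.5) {
  check_positive(buoyant_density, "buoyant_density")
  check_fraction(intracellular_fraction, "intracellular_fraction")
  check_fraction(cytosol_of_intracellular, "cytosol_of_intracellular")
  structure(
    list(
      buoyant_density = buoyant_density,
      intracellular_fraction = intracellular_fraction,
      cytosol_of_intracellular = cytosol_of_intracellular,
      cytosol_fraction = intracellular_fraction * cytosol_of_intracellular
    ),
    class = "cell_volume_model"
  )
}

#' Packed cell volume from packed cell mass
#'
#' @param mass_mg Packed cell mass in mg.
#' @param model A [cell_volume_model()].
#' @return Packed cell volume in µl (mg over g/ml is µl).
#' @export
packed_volume_from_mass <- function(mass_mg, model = cell_volume_model()) {
  check_positive(mass_mg, "mass_mg", strict = FALSE)
  mass_mg / model$buoyant_density
}

new_calibration_curve <- function(slope, intercept, linear_range_max,
                                  n_standards, r_squared, standards,
                                  excluded) {
  structure(
    list(slope = slope, intercept = intercept,
         linear_range_max = linear_range_max, n_standards = n_standards,
         r_squared = r_squared, standards = standards, excluded = excluded),
    class = "calibration_curve"
  )
}

#' Fit an immunoblot standard curve with saturation detection
#'
#' Least-squares line of signal on mass over the standards that lie in
#' the linear range. Saturation detection drops the largest-mass
#' standard while the top point falls below the line refit on the rest
#' by more than `saturation_tol` (relative residual), mirroring manual
#' exclusion of saturated lanes. The intercept is free by default (blots
#' have nonzero background).
#'
#' @param standards Data frame of known loadings.
#' @param mass,signal Column names (mass in pmol; signal arbitrary
#'   fluorescence units).
#' @param saturation_tol Relative shortfall of the top standard below
#'   the line refit on the others that triggers exclusion (default 0.1).
#' @param intercept `"free"` (default) or `"origin"`.
#' @return A `calibration_curve` with `slope` (signal per pmol, > 0),
#'   `intercept`, `linear_range_max` (largest in-range signal),
#'   `r_squared`, the retained standards and any `excluded` ones.
#' @export
fit_calibration <- function(standards, mass = "mass_pmol",
                            signal = "signal", saturation_tol = 0.1,
                            intercept = c("free", "origin")) {
  intercept <- match.arg(intercept)
  check_columns(standards, c(mass, signal), "standards table")
  std <- tibble::tibble(mass_pmol = standards[[mass]],
                        signal = standards[[signal]])
  check_positive(std$mass_pmol, "mass_pmol")
  check_positive(std$signal, "signal", strict = FALSE)
  if (all(std$signal == 0)) {
    abort("all standards have zero signal; no calibration possible",
          class = "holophos_input_error")
  }
  std <- dplyr::arrange(std, .data$mass_pmol)

  line_fit <- function(d) {
    if (intercept == "free") lm(signal ~ mass_pmol, data = d)
    else lm(signal ~ 0 + mass_pmol, data = d)
  }

  kept <- std
  repeat {
    if (nrow(kept) < 3) {
      abort(sprintf(
        "fewer than 3 standards remain in the linear range (%d); calibration rejected",
        nrow(kept)
      ), class = "holophos_input_error")
    }
    top <- nrow(kept)
    ref <- line_fit(kept[-top, , drop = FALSE])
    pred_top <- predict(ref, newdata = kept[top, , drop = FALSE])
    shortfall <- (pred_top - kept$signal[top]) / pred_top
    if (is.finite(shortfall) && shortfall > saturation_tol) {
      kept <- kept[-top, , drop = FALSE]
    } else {
      break
    }
  }
  fit <- line_fit(kept)
  sm <- quiet_summary(fit)
  slope <- unname(coef(fit)[[length(coef(fit))]])
  if (slope <= 0) {
    abort("calibration slope is not positive; standards do not form a usable curve",
          class = "holophos_input_error")
  }
  new_calibration_curve(
    slope = slope,
    intercept = if (intercept == "free") unname(coef(fit)[[1]]) else 0,
    linear_range_max = max(kept$signal),
    n_standards = nrow(kept),
    r_squared = sm$r.squared,
    standards = kept,
    excluded = dplyr::anti_join(std, kept, by = c("mass_pmol", "signal"))
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> signal = %.4g + %.4g * mass_pmol (R^2 %.4f, %d standards, linear up to signal %.4g%s)\n",
    x$intercept, x$slope, x$r_squared, x$n_standards, x$linear_range_max,
    if (nrow(x$excluded) > 0) {
      sprintf("; %d saturated standard(s) excluded", nrow(x$excluded))
    } else ""
  ))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    units = c("signal", "signal_per_pmol")
  )
}

#' @rdname fit_calibration
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, n_standards = x$n_standards,
    linear_range_max = x$linear_range_max, n_excluded = nrow(x$excluded)
  )
}

#' Plot a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot object; excluded (saturated) standards are drawn as
#'   open circles.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$mass_pmol, y = .data$signal)) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$excluded, shape = 1,
                        colour = "grey60") +
    ggplot2::labs(x = "recombinant protein (pmol)",
                  y = "fluorescent signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Convert a lane signal to protein mass via a calibration curve
#'
#' Inverse-linear interpolation, valid only inside the curve's linear
#' range; saturated signals are rejected (the standard curve carries no
#' information above its linear ceiling).
#'
#' @param signal Fluorescence signal(s), arbitrary units.
#' @param curve A [fit_calibration()] result.
#' @return Mass in pmol.
#' @export
lane_to_moles <- function(signal, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(signal < curve$intercept)) {
    abort("signal below the calibration intercept; mass would be negative",
          class = "holophos_input_error")
  }
  over <- signal > curve$linear_range_max
  if (any(over)) {
    abort(sprintf(
      "%d signal(s) above the linear range maximum (%.4g); saturated lanes cannot be quantified",
      sum(over), curve$linear_range_max
    ), class = "holophos_saturation_error")
  }
  (signal - curve$intercept) / curve$slope
}

#' Cytosolic concentration from protein mass and packed cell volume
#'
#' Divides the measured mass by the cytosolic volume of the loaded
#' packed cells (`packed_cell_volume * intracellular_fraction *
#' cytosol_of_intracellular`, 30% by default).
#'
#' @param moles_pmol Protein mass in pmol (>= 0).
#' @param packed_cell_volume_ul Packed cell volume loaded, in µl (> 0).
#' @param model A [cell_volume_model()].
#' @return Concentration in µM.
#' @export
#' @examples
#' concentration_from_moles(0.5, 5)  # 0.5 pmol / 1.5 ul cytosol = 0.333 uM
concentration_from_moles <- function(moles_pmol, packed_cell_volume_ul,
                                     model = cell_volume_model()) {
  check_positive(moles_pmol, "moles_pmol", strict = FALSE)
  check_positive(packed_cell_volume_ul, "packed_cell_volume_ul")
  moles_pmol / (packed_cell_volume_ul * model$cytosol_fraction)
}

#' Cytosolic concentration from molecules per cell
#'
#' Converts a copy number per cell to a molar cytosolic concentration:
#' `n / (N_A * V_cell * cytosol_fraction)`, reported in µM. With the
#' canonical yeast numbers (1.71e4 molecules, 60 fl cells, half cytosol)
#' this gives 0.95 µM.
#'
#' @param n_molecules Molecules per cell (>= 0).
#' @param cell_volume_fl Cell volume in femtolitres (> 0).
#' @param cytosol_fraction Fraction of the cell volume that is cytosol,
#'   in (0, 1].
#' @return Concentration in µM.
#' @export
#' @examples
#' molecules_to_concentration(1.71e4, 60, 0.5)
molecules_to_concentration <- function(n_molecules, cell_volume_fl,
                                       cytosol_fraction = 0.5) {
  check_positive(n_molecules, "n_molecules", strict = FALSE)
  check_positive(cell_volume_fl, "cell_volume_fl")
  check_fraction(cytosol_fraction, "cytosol_fraction")
  avogadro <- 6.02214076e23
  moles <- n_molecules / avogadro
  litres <- cell_volume_fl * 1e-15 * cytosol_fraction
  (moles / litres) * 1e6
}

#' Per-sample cytosolic concentration from lysate immunoblot lanes
#'
#' Converts each in-range lysate lane signal to mass via the calibration
#' curve, divides by the lane's cytosolic volume, and summarises per
#' sample as mean ± SD across accepted lanes. Saturated lanes are
#' excluded (and counted), mirroring the use of only unsaturated
#' loadings.
#'
#' @param lysate Data frame with columns `sample_id`, `signal` and either
#'   `packed_cell_volume_ul` or `packed_cell_mass_mg` (converted via the
#'   model's buoyant density).
#' @param curve A [fit_calibration()] result.
#' @param model A [cell_volume_model()].
#' @return Tibble per sample: `concentration_uM` (mean), `sd_uM`,
#'   `n_lanes` (accepted), `n_saturated` (above the linear range) and
#'   `n_below_range` (below the curve intercept; too faint to quantify).
#' @export
estimate_abundance <- function(lysate, curve, model = cell_volume_model()) {
  check_columns(lysate, c("sample_id", "signal"), "lysate table")
  if (!"packed_cell_volume_ul" %in% names(lysate)) {
    check_columns(lysate, "packed_cell_mass_mg", "lysate table")
    lysate <- dplyr::mutate(
      lysate,
      packed_cell_volume_ul = packed_volume_from_mass(
        .data$packed_cell_mass_mg, model
      )
    )
  }
  lysate |>
    dplyr::mutate(
      saturated = .data$signal > curve$linear_range_max,
      too_faint = .data$signal < curve$intercept,
      conc = dplyr::if_else(
        .data$saturated | .data$too_faint, NA_real_,
        (.data$signal - curve$intercept) / curve$slope /
          (.data$packed_cell_volume_ul * model$cytosol_fraction)
      )
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      concentration_uM = mean(.data$conc, na.rm = TRUE),
      sd_uM = sd(.data$conc, na.rm = TRUE),
      n_lanes = sum(!is.na(.data$conc)),
      n_saturated = sum(.data$saturated),
      n_below_range = sum(.data$too_faint),
      .groups = "drop"
    )
}
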
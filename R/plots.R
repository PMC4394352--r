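# Figure-style diagnostics.

#' Plot log-decay time courses with their fitted lines
#'
#' The standard first-order diagnostic: `ln(S0/St)` against time, one
#' panel series per starting substrate concentration, with the fitted
#' through-origin line. Linearity with a common slope across starting
#' concentrations is the signature of first-order kinetics.
#'
#' @param quantified Output of [quantify_lanes()].
#' @param decay_rates Output of [fit_decay_rates()] on the same table.
#' @return A ggplot object.
#' @export
plot_log_decay <- function(quantified, decay_rates) {
  series <- quantified |>
    dplyr::group_by(.data$condition_label, .data$replicate_id,
                    .data$substrate_total_uM) |>
    dplyr::group_modify(function(d, g) {
      log_decay_series(d, s0 = g$substrate_total_uM)
    }) |>
    dplyr::ungroup()
  lines <- dplyr::select(decay_rates, "condition_label", "replicate_id",
                         "substrate_total_uM", "k_per_min")
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time_min, y = .data$log_ratio,
                               colour = factor(.data$substrate_total_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = 0, slope = .data$k_per_min,
                   colour = factor(.data$substrate_total_uM))
    ) +
    ggplot2::labs(x = "time (min)", y = "ln(S0/St)",
                  colour = "S0 (uM)") +
    ggplot2::theme_minimal()
}

#' Plot initial velocity against starting substrate concentration
#'
#' Sub-Km the relation is linear through the origin and its slope is
#' proportional to kcat/Km.
#'
#' @param velocities Output of [compute_initial_velocities()].
#' @param slope Optional `slope_estimate` from [velocity_vs_substrate()]
#'   drawn as a through-origin line.
#' @return A ggplot object.
#' @export
plot_velocity_vs_substrate <- function(velocities, slope = NULL) {
  p <- ggplot2::ggplot(velocities,
                       ggplot2::aes(x = .data$s0_uM, y = .data$vi,
                                    colour = .data$condition_label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "S0 (uM)", y = "initial velocity (per min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(slope)) {
    p <- p + ggplot2::geom_abline(intercept = 0, slope = slope$slope,
                                  colour = "grey40")
  }
  p
}
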
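# First-order kinetic analysis of dephosphorylation time courses.
#
# Sub-Km, a Michaelis-Menten reaction is pseudo-first-order in substrate:
# S(t) = S0 * exp(-k t). The log-transformed course ln(S0/St) is then
# linear in time with slope k, and the integrated rate equation gives the
# initial velocity Vi = ln(S0/Sf) * S0 / (dt * [ENZ]) — substrate turned
# over per molecule of enzyme per minute.

#' Log-transformed substrate decay series
#'
#' Computes `ln(S0/St)` (optionally `log10`) at each time point of a
#' dephosphorylation time course. The value is exactly 0 wherever
#' `St = S0`.
#'
#' @param data Data frame with one row per time point.
#' @param time,substrate Columns holding time (minutes) and remaining
#'   substrate concentration (µM). Defaults match the output of
#'   [quantify_lanes()].
#' @param s0 Substrate concentration at t = 0 (µM). Default: taken from a
#'   `substrate_total_uM` column if present, otherwise from the
#'   `time == 0` row.
#' @param base10 If `TRUE`, report `log10` values (figure-style view);
#'   the natural log is used internally and slope ratios are
#'   base-invariant.
#' @param s0_tolerance Relative tolerance for `St > S0` before a point is
#'   flagged as exceeding the starting concentration (noise allowance).
#' @return Tibble with `time_min`, `log_ratio` and a logical
#'   `exceeds_s0` flag; negative transformed values are retained with a
#'   warning, not dropped.
#' @export
log_decay_series <- function(data, time = "time_min",
                             substrate = "substrate_uM", s0 = NULL,
                             base10 = FALSE, s0_tolerance = 0.05) {
  check_columns(data, c(time, substrate), "time course")
  t_min <- data[[time]]
  st <- data[[substrate]]
  if (is.null(s0)) {
    if ("substrate_total_uM" %in% names(data)) {
      s0 <- unique(data$substrate_total_uM)
      if (length(s0) != 1) {
        abort("multiple substrate_total_uM values in one time course; supply `s0` or split by condition",
              class = "holophos_input_error")
      }
    } else if (any(t_min == 0)) {
      s0 <- st[t_min == 0][1]
    } else {
      abort("cannot infer S0: no substrate_total_uM column and no t = 0 point; supply `s0`",
            class = "holophos_input_error")
    }
  }
  check_positive(s0, "s0")
  if (any(st <= 0)) {
    abort(sprintf(
      "non-positive substrate concentration at time(s) %s; the log decay transform requires St > 0",
      paste(t_min[st <= 0], collapse = ", ")
    ), class = "holophos_input_error")
  }
  exceeds <- st > s0 * (1 + s0_tolerance)
  if (any(exceeds)) {
    warn(sprintf(
      "substrate exceeds S0 beyond tolerance at time(s) %s; negative log-ratios retained",
      paste(t_min[exceeds], collapse = ", ")
    ), class = "holophos_exceeds_s0_warning")
  }
  lr <- log(s0 / st)
  if (base10) lr <- lr / log(10)
  tibble::tibble(time_min = t_min, log_ratio = lr, exceeds_s0 = exceeds)
}

#' Fit a first-order rate constant to a time course
#'
#' Least-squares line on `(time, ln(S0/St))`. Through-origin by default
#' (the t = 0 point is identically zero by construction, so `dof = n - 1`);
#' a free-intercept mode is available for diagnostics (`dof = n - 2`). On
#' noiseless exponential input the true rate constant is recovered
#' exactly with `r_squared = 1`.
#'
#' @inheritParams log_decay_series
#' @param intercept `"origin"` (default) or `"free"`.
#' @param label Optional condition label carried into the estimate.
#' @return A [`slope_estimate`][tidy.slope_estimate] whose slope is the
#'   rate constant k (per minute).
#' @export
fit_first_order <- function(data, time = "time_min",
                            substrate = "substrate_uM", s0 = NULL,
                            intercept = c("origin", "free"),
                            s0_tolerance = 0.05, label = NA_character_) {
  intercept <- match.arg(intercept)
  series <- log_decay_series(data, time = time, substrate = substrate,
                             s0 = s0, s0_tolerance = s0_tolerance)
  usable <- series$time_min >= 0
  series <- series[usable, , drop = FALSE]
  if (sum(series$time_min > 0) < 2) {
    abort("at least 2 time points with time > 0 are required",
          class = "holophos_input_error")
  }
  # the t = 0 anchor is exact and adds nothing to a through-origin fit
  if (intercept == "origin") {
    series <- series[series$time_min > 0, , drop = FALSE]
  }
  fit_slope(series$time_min, series$log_ratio, mode = intercept,
            units = "per_min", label = label)
}

#' Initial velocity from the integrated first-order rate equation
#'
#' `Vi = ln(S0/Sf) * S0 / (dt * [ENZ])`: the instantaneous rate of
#' substrate conversion per molecule of enzyme at t = 0, valid at
#' substrate concentrations well below Km. On exact first-order data
#' `Vi = k * S0 / [ENZ]` and is independent of the interval `dt`.
#'
#' @param s0,sf Substrate concentration (µM) at the beginning and end of
#'   the interval; both must be positive.
#' @param dt_min Interval length in minutes (> 0).
#' @param enzyme_uM Enzyme concentration in µM (> 0).
#' @param max_depletion Depletion fraction `(S0 - Sf)/S0` above which the
#'   first-order estimate is considered out of its validity range
#'   (default 0.25); offending values trigger a classed warning.
#' @return Numeric vector of velocities (per minute). Values where
#'   `Sf > S0` are negative and flagged with a warning, never clamped
#'   (silent clamping biases downstream ratio statistics).
#' @export
#' @examples
#' initial_velocity(2, 2 * exp(-0.5), dt_min = 5, enzyme_uM = 0.025)  # 8
initial_velocity <- function(s0, sf, dt_min, enzyme_uM,
                             max_depletion = 0.25) {
  check_positive(s0, "s0")
  check_positive(sf, "sf")
  check_positive(dt_min, "dt_min")
  check_positive(enzyme_uM, "enzyme_uM")
  depletion <- (s0 - sf) / s0
  if (any(depletion > max_depletion)) {
    warn(sprintf(
      "substrate depletion exceeds %.0f%% for %d point(s); the first-order initial-velocity estimate is outside its validity range",
      100 * max_depletion, sum(depletion > max_depletion)
    ), class = "holophos_depletion_warning")
  }
  if (any(sf > s0)) {
    warn("Sf > S0: negative velocity reported (not clamped)",
         class = "holophos_negative_velocity_warning")
  }
  log(s0 / sf) * s0 / (dt_min * enzyme_uM)
}

#' Per-condition initial velocities from a quantified lane table
#'
#' Single-time-point mode: for each condition / replicate / starting
#' concentration, Vi is computed from the lane at `time_point` minutes
#' (the early point at which excess substrate remains).
#'
#' @param quantified Output of [quantify_lanes()].
#' @param time_point Time (minutes) of the lane used (default 5).
#' @param max_depletion Passed to [initial_velocity()].
#' @return Tibble with one row per condition x replicate x S0:
#'   `condition_label`, `replicate_id`, `s0_uM`, `enzyme_uM`,
#'   `effector_uM`, `vi`, `depletion`, `over_depleted`.
#' @export
compute_initial_velocities <- function(quantified, time_point = 5,
                                       max_depletion = 0.25) {
  check_columns(
    quantified,
    c("condition_label", "replicate_id", "substrate_total_uM",
      "enzyme_uM", "effector_uM", "time_min", "substrate_uM"),
    "quantified lane table"
  )
  pts <- dplyr::filter(quantified, .data$time_min == time_point)
  if (nrow(pts) == 0) {
    abort(sprintf("no lanes at time_point = %s min", time_point),
          class = "holophos_input_error")
  }
  dplyr::transmute(
    pts,
    condition_label = .data$condition_label,
    replicate_id = .data$replicate_id,
    s0_uM = .data$substrate_total_uM,
    enzyme_uM = .data$enzyme_uM,
    effector_uM = .data$effector_uM,
    vi = initial_velocity(.data$substrate_total_uM, .data$substrate_uM,
                          dt_min = time_point, enzyme_uM = .data$enzyme_uM,
                          max_depletion = max_depletion),
    depletion = (.data$substrate_total_uM - .data$substrate_uM) /
      .data$substrate_total_uM,
    over_depleted = .data$depletion > max_depletion
  )
}

#' Specificity-constant-proportional slope from velocity vs substrate
#'
#' Sub-Km, Vi grows linearly with S0 and the through-origin slope of Vi
#' against S0 is proportional to kcat/Km of the enzyme-substrate pair
#' (it equals `k / [ENZ]` on exact first-order data). Km and Vmax are
#' deliberately not estimated: the assays cannot saturate the enzyme.
#'
#' @param data Data frame of initial velocities, e.g. from
#'   [compute_initial_velocities()].
#' @param substrate,velocity Column names for S0 (µM) and Vi (per min).
#' @param intercept `"origin"` (default; Vi -> 0 as S0 -> 0 sub-Km) or
#'   `"free"`.
#' @param label Optional condition label.
#' @return A `slope_estimate` in per-minute-per-µM units.
#' @export
velocity_vs_substrate <- function(data, substrate = "s0_uM",
                                  velocity = "vi",
                                  intercept = c("origin", "free"),
                                  label = NA_character_) {
  intercept <- match.arg(intercept)
  check_columns(data, c(substrate, velocity), "velocity table")
  s <- data[[substrate]]
  v <- data[[velocity]]
  if (length(unique(s)) < 2) {
    abort("at least 2 distinct substrate concentrations are required",
          class = "holophos_input_error")
  }
  fit_slope(s, v, mode = intercept, units = "per_min_per_uM", label = label)
}

#' Fit first-order rate constants for every condition in a lane table
#'
#' Groups a quantified lane table by condition, replicate and starting
#' substrate concentration and fits [fit_first_order()] to each group.
#'
#' @inheritParams compute_initial_velocities
#' @param intercept Passed to [fit_first_order()].
#' @return Tibble with one row per group: grouping columns plus the
#'   tidied slope estimate (rate constant `k` per minute).
#' @export
fit_decay_rates <- function(quantified, intercept = c("origin", "free")) {
  intercept <- match.arg(intercept)
  check_columns(
    quantified,
    c("condition_label", "replicate_id", "substrate_total_uM",
      "enzyme_uM", "time_min", "substrate_uM"),
    "quantified lane table"
  )
  quantified |>
    dplyr::group_by(.data$condition_label, .data$replicate_id,
                    .data$substrate_total_uM, .data$enzyme_uM) |>
    dplyr::group_modify(function(d, g) {
      tidy(fit_first_order(d, s0 = g$substrate_total_uM,
                           intercept = intercept,
                           label = g$condition_label))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(k_per_min = "estimate")
}
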
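# G-actin dose-response: hyperbolic activation of dephosphorylation
# velocity, v(A) = v0 + (vmax - v0) * A / (EC50 + A).
#
# At the highest G-actin concentrations the stimulatory effect can
# decline (actin polymerisation during the assay); no mechanistic model
# is fitted for the decline — offending doses can be excluded and are
# then listed on the fit.

new_dose_response_fit <- function(v0, vmax, ec50, hill, residual_sd,
                                  n_points, excluded, data, converged,
                                  flags = character()) {
  structure(
    list(v0 = v0, vmax = vmax, ec50 = ec50, hill = hill,
         residual_sd = residual_sd, n_points = n_points,
         excluded = excluded, data = data, converged = converged,
         flags = flags),
    class = "dose_response_fit"
  )
}

#' Fit a hyperbolic effector-activation curve and report EC50
#'
#' Least-squares fit of `v(A) = v0 + (vmax - v0) * A / (EC50 + A)`
#' (Hill exponent fixed at 1 by default, optionally free) to velocities
#' measured across a G-actin dose series.
#'
#' Starting values are deterministic: `v0` from the zero dose, `vmax`
#' from the largest velocity, `EC50` from the dose whose velocity is
#' nearest half-range.
#'
#' @param data Data frame of doses and velocities.
#' @param dose,velocity Column names (dose in µM, velocity per minute).
#' @param exclude_above Doses strictly above this value (µM) are omitted
#'   from the fit and listed in `excluded` (default `NULL`: none), the
#'   standard handling for the high-dose decline.
#' @param hill `"fixed"` (exponent 1) or `"free"`.
#' @return A `dose_response_fit` with `v0`, `vmax`, `ec50` (µM), `hill`,
#'   `residual_sd`, `n_points`, `excluded`. A flat response (no dose
#'   dependence) yields `ec50 = NA` with flag `"flat_response"`; the
#'   other parameters are then the mean velocity.
#' @export
fit_activation <- function(data, dose = "dose_uM", velocity = "velocity",
                           exclude_above = NULL, hill = c("fixed", "free")) {
  hill <- match.arg(hill)
  check_columns(data, c(dose, velocity), "dose table")
  full <- tibble::tibble(dose_uM = data[[dose]], velocity = data[[velocity]])
  check_positive(full$dose_uM, "dose", strict = FALSE)

  excluded <- full[0, , drop = FALSE]
  if (!is.null(exclude_above)) {
    keep <- full$dose_uM <= exclude_above
    excluded <- full[!keep, , drop = FALSE]
    full <- full[keep, , drop = FALSE]
  }
  if (length(unique(full$dose_uM)) < 4 || !any(full$dose_uM == 0)) {
    abort("at least 4 dose levels including a zero dose are required",
          class = "holophos_input_error")
  }

  v <- full$velocity
  a <- full$dose_uM
  v_range <- diff(range(v))
  if (v_range <= 1e-10 * max(abs(v), 1e-300)) {
    return(new_dose_response_fit(
      v0 = mean(v), vmax = mean(v), ec50 = NA_real_,
      hill = if (hill == "fixed") 1 else NA_real_,
      residual_sd = sd(v), n_points = nrow(full), excluded = excluded,
      data = full, converged = TRUE, flags = "flat_response"
    ))
  }

  start <- list(
    v0 = mean(v[a == 0]),
    vmax = max(v),
    ec50 = max(a[which.min(abs(v - (min(v) + v_range / 2)))], min(a[a > 0]))
  )
  fit <- tryCatch(
    if (hill == "fixed") {
      minpack.lm::nlsLM(
        velocity ~ v0 + (vmax - v0) * dose_uM / (ec50 + dose_uM),
        data = full, start = start,
        lower = c(v0 = -Inf, vmax = -Inf, ec50 = .Machine$double.eps),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        velocity ~ v0 + (vmax - v0) * dose_uM^h / (ec50^h + dose_uM^h),
        data = full, start = c(start, h = 1),
        lower = c(v0 = -Inf, vmax = -Inf, ec50 = .Machine$double.eps,
                  h = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) {
      abort(
        sprintf(
          "dose-response fit failed to converge: %s (n = %d doses, velocity range %.3g to %.3g, starts v0 = %.3g, vmax = %.3g, ec50 = %.3g)",
          conditionMessage(e), nrow(full), min(v), max(v),
          start$v0, start$vmax, start$ec50
        ),
        class = "holophos_fit_error"
      )
    }
  )
  est <- coef(fit)
  flags <- character()
  # a fit that converged onto a flat curve has no identifiable EC50
  if (abs(est["vmax"] - est["v0"]) <= 1e-6 * max(abs(v))) {
    est["ec50"] <- NA_real_
    flags <- "flat_response"
  }
  new_dose_response_fit(
    v0 = unname(est["v0"]), vmax = unname(est["vmax"]),
    ec50 = unname(est["ec50"]),
    hill = if (hill == "fixed") 1 else unname(est["h"]),
    residual_sd = sqrt(sum(resid(fit)^2) / max(1, nrow(full) - length(est))),
    n_points = nrow(full), excluded = excluded, data = full,
    converged = TRUE, flags = flags
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> v0 = %.4g, vmax = %.4g, EC50 = %s uM, Hill = %.3g (n = %d%s)\n",
    x$v0, x$vmax,
    ifelse(is.na(x$ec50), "undefined", sprintf("%.4g", x$ec50)),
    x$hill, x$n_points,
    if (nrow(x$excluded) > 0) {
      sprintf("; %d high-dose point(s) excluded", nrow(x$excluded))
    } else ""
  ))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy or summarise a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: one-row fit
#'   summary.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v0", "vmax", "ec50", "hill"),
    estimate = c(x$v0, x$vmax, x$ec50, x$hill),
    units = c("per_min", "per_min", "uM", "")
  )
}

#' @rdname tidy.dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    ec50_uM = x$ec50, residual_sd = x$residual_sd, n = x$n_points,
    n.excluded = nrow(x$excluded), converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Plot a dose-response fit
#'
#' Points (fitted in black, excluded in open grey) with the fitted
#' activation curve; dose axis on log10 scale with the zero dose shown
#' at a pseudo-dose.
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pos <- object$data$dose_uM[object$data$dose_uM > 0]
  pseudo <- if (length(pos) > 0) min(pos) / 4 else 1e-3
  shown <- dplyr::mutate(
    object$data,
    dose_plot = ifelse(.data$dose_uM == 0, pseudo, .data$dose_uM)
  )
  grid <- tibble::tibble(
    dose_uM = exp(seq(log(pseudo), log(max(shown$dose_plot)),
                      length.out = 200))
  )
  h <- object$hill
  grid$velocity <- object$v0 + (object$vmax - object$v0) *
    grid$dose_uM^h / (ifelse(is.na(object$ec50), Inf, object$ec50)^h +
                        grid$dose_uM^h)
  p <- ggplot2::ggplot(shown,
                       ggplot2::aes(x = .data$dose_plot,
                                    y = .data$velocity)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$dose_uM, y = .data$velocity),
                       colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "G-actin (uM, log scale; zero dose at left edge)",
                  y = "initial velocity (per min)") +
    ggplot2::theme_minimal()
  if (nrow(object$excluded) > 0) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(object$excluded, dose_plot = .data$dose_uM),
      shape = 1, colour = "grey60"
    )
  }
  p
}
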
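# slope_estimate: the unit of all downstream ratio statistics.

new_slope_estimate <- function(slope, stderr, dof, r_squared, n_points,
                               intercept = 0, mode = "origin",
                               units = "per_min", flags = character(),
                               label = NA_character_) {
  structure(
    list(
      slope = slope, stderr = stderr, dof = dof, r_squared = r_squared,
      n_points = n_points, intercept = intercept, mode = mode,
      units = units, flags = flags, label = label
    ),
    class = "slope_estimate"
  )
}

# Accept a slope_estimate or a bare list/numeric triple in ratio statistics.
as_slope_estimate <- function(x, arg = "x") {
  if (inherits(x, "slope_estimate")) return(x)
  if (is.list(x) && all(c("slope", "stderr", "dof") %in% names(x))) {
    return(new_slope_estimate(
      slope = x$slope, stderr = x$stderr, dof = x$dof,
      r_squared = x$r_squared %||% NA_real_,
      n_points = x$n_points %||% NA_integer_,
      label = x$label %||% NA_character_
    ))
  }
  abort(sprintf(
    "`%s` must be a slope_estimate or a list with slope, stderr and dof",
    arg
  ), class = "holophos_input_error")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf(
    "<slope_estimate%s> slope = %.6g +/- %.3g %s (dof %s, n %s, R^2 %s, %s)\n",
    if (is.na(x$label)) "" else paste0(": ", x$label),
    x$slope, x$stderr, x$units, format(x$dof), format(x$n_points),
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    x$mode
  ))
  if (length(x$flags) > 0) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted slope estimate
#'
#' @param x A `slope_estimate`.
#' @param ... Unused.
#' @return One-row tibble with estimate, standard error, dof, fit quality
#'   and flags.
#' @export
tidy.slope_estimate <- function(x, ...) {
  tibble::tibble(
    term = "slope",
    estimate = x$slope,
    std.error = x$stderr,
    dof = x$dof,
    r.squared = x$r_squared,
    n = x$n_points,
    units = x$units,
    mode = x$mode,
    flags = paste(x$flags, collapse = ";"),
    label = x$label
  )
}

#' @rdname tidy.slope_estimate
#' @export
glance.slope_estimate <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, dof = x$dof, n = x$n_points,
    n.flags = length(x$flags)
  )
}

# Least-squares line shared by the decay and velocity regressions.
# Through-origin by default: the anchor point (0, 0) is exact by
# construction in both settings, so it carries no error and the fit
# spends no dof on an intercept.
fit_slope <- function(x, y, mode = c("origin", "free"), units, label) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 2) {
    abort("at least 2 points are required for a slope fit",
          class = "holophos_input_error")
  }
  if (length(unique(x)) < 2) {
    abort("all predictor values are identical; slope is undefined",
          class = "holophos_input_error")
  }
  fit <- if (mode == "origin") lm(y ~ 0 + x) else lm(y ~ x)
  sm <- quiet_summary(fit)
  slope_row <- sm$coefficients["x", ]
  new_slope_estimate(
    slope = unname(slope_row["Estimate"]),
    stderr = unname(slope_row["Std. Error"]),
    dof = fit$df.residual,
    r_squared = sm$r.squared,
    n_points = n,
    intercept = if (mode == "free") unname(coef(fit)[1]) else 0,
    mode = mode, units = units, label = label
  )
}
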
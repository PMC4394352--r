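# Fold-change statistics on slope estimates.
#
# The estimand throughout is a ratio of fitted slopes (relative
# velocities, proportional to kcat/Km). Intervals on a ratio of two
# normal estimates come from Fieller's theorem, which is exact under
# normality and naturally asymmetric; the four-way specificity factor
# uses a log-scale delta method.

new_ratio_estimate <- function(ratio, ci_low, ci_high, level, method_label,
                               flags = character(), inputs = NULL) {
  structure(
    list(ratio = ratio, ci_low = ci_low, ci_high = ci_high, level = level,
         method_label = method_label, flags = flags, inputs = inputs),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "<ratio_estimate> %.4g (%.0f%% CI %.4g to %.4g; %s)\n",
    x$ratio, 100 * x$level, x$ci_low, x$ci_high, x$method_label
  ))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a ratio estimate or specificity factor
#'
#' @param x A `ratio_estimate` or `specificity_factor`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, confidence limits, level,
#'   method label and flags.
#' @export
tidy.ratio_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$ratio, conf.low = x$ci_low, conf.high = x$ci_high,
    conf.level = x$level, method = x$method_label,
    flags = paste(x$flags, collapse = ";")
  )
}

# dof pooling. For the two-estimate Fieller ratio the common dof is
# used when both inputs share it (this matches a parametric bootstrap
# of the ratio of t-scaled estimates almost exactly), Welch-
# Satterthwaite when they differ. For a summed variance of several
# components (the log-delta specificity factor) Satterthwaite's
# effective dof is the standard choice throughout.
pool_dof <- function(vars, dofs) {
  if (length(unique(dofs)) == 1) return(dofs[1])
  ws_dof(vars, dofs)
}

ws_dof <- function(vars, dofs) {
  sum(vars)^2 / sum(vars^2 / dofs)
}

#' Ratio of two slope estimates with a Fieller confidence interval
#'
#' Computes `num/den` with confidence limits from Fieller's theorem,
#' using a t quantile at the inputs' common dof (Welch-Satterthwaite
#' pooled when the dofs differ). The interval is generally asymmetric
#' about the ratio. When the denominator is not significantly nonzero at
#' the chosen level, Fieller's construction gives no finite interval and
#' the result is flagged `"unbounded"` with infinite limits rather than
#' silently truncated.
#'
#' @param num,den `slope_estimate` objects (or lists with `slope`,
#'   `stderr`, `dof`); independent estimates.
#' @param level Confidence level (default 0.95).
#' @return A `ratio_estimate`. Degenerate zero-variance inputs give a
#'   point interval.
#' @export
slope_ratio <- function(num, den, level = 0.95) {
  num <- as_slope_estimate(num, "num")
  den <- as_slope_estimate(den, "den")
  check_fraction(level, "level")
  if (den$slope == 0) {
    abort("denominator slope is zero; ratio undefined",
          class = "holophos_input_error")
  }
  if (num$stderr < 0 || den$stderr < 0) {
    abort("standard errors must be non-negative",
          class = "holophos_input_error")
  }
  a <- num$slope; sa <- num$stderr
  b <- den$slope; sb <- den$stderr
  r <- a / b
  inputs <- list(num = num, den = den)

  if (sa == 0 && sb == 0) {
    return(new_ratio_estimate(r, r, r, level, "fieller_t",
                              flags = "zero_variance", inputs = inputs))
  }
  vars <- c(sa^2, r^2 * sb^2)
  dof <- pool_dof(vars, c(num$dof, den$dof))
  tq <- qt(1 - (1 - level) / 2, dof)
  g <- (tq * sb / b)^2
  if (g >= 1) {
    return(new_ratio_estimate(
      r, -Inf, Inf, level, "fieller_t",
      flags = "unbounded", inputs = inputs
    ))
  }
  disc <- a^2 * sb^2 + b^2 * sa^2 - tq^2 * sa^2 * sb^2
  half <- tq * sqrt(disc)
  lims <- (a * b + c(-1, 1) * half) / (b^2 - tq^2 * sb^2)
  new_ratio_estimate(r, min(lims), max(lims), level, "fieller_t",
                     inputs = inputs)
}

#' Specificity factor of a mutant substrate, normalised to wildtype
#'
#' `SF = (V_TC(mut) / V_BC(mut)) / (V_TC(wt) / V_BC(wt))`: the ratio of a
#' substrate's ternary-complex (actin-containing holophosphatase) to
#' binary-complex dephosphorylation velocity, normalised so that the
#' wildtype substrate scores exactly 1. SF < 1 means the mutation
#' selectively compromises the substrate for the specific (ternary)
#' enzyme.
#'
#' The confidence interval is a log-scale delta-method propagation of
#' the four slope standard errors with a t quantile at the pooled dof.
#'
#' @param v_tc_mut,v_bc_mut,v_tc_wt,v_bc_wt `slope_estimate` objects for
#'   the mutant and wildtype substrate under the ternary (TC) and binary
#'   (BC) complexes. All four slopes must be positive.
#' @param level Confidence level (default 0.95).
#' @return A `specificity_factor` object (also a `ratio_estimate`).
#' @export
specificity_factor <- function(v_tc_mut, v_bc_mut, v_tc_wt, v_bc_wt,
                               level = 0.95) {
  args <- list(v_tc_mut = v_tc_mut, v_bc_mut = v_bc_mut,
               v_tc_wt = v_tc_wt, v_bc_wt = v_bc_wt)
  ests <- purrr::imap(args, as_slope_estimate)
  bad <- names(ests)[purrr::map_lgl(ests, \(e) e$slope <= 0)]
  if (length(bad) > 0) {
    abort(sprintf("non-positive slope in: %s", paste(bad, collapse = ", ")),
          class = "holophos_input_error")
  }
  check_fraction(level, "level")
  sf <- (ests$v_tc_mut$slope / ests$v_bc_mut$slope) /
    (ests$v_tc_wt$slope / ests$v_bc_wt$slope)
  cv2 <- purrr::map_dbl(ests, \(e) (e$stderr / e$slope)^2)
  se_log <- sqrt(sum(cv2))
  flags <- character()
  if (se_log == 0) {
    lims <- c(sf, sf)
    flags <- "zero_variance"
  } else {
    dof <- ws_dof(cv2[cv2 > 0],
                  purrr::map_dbl(ests, "dof")[cv2 > 0])
    tq <- qt(1 - (1 - level) / 2, dof)
    lims <- sf * exp(c(-1, 1) * tq * se_log)
  }
  out <- new_ratio_estimate(sf, lims[1], lims[2], level,
                            "log_delta_t", flags = flags, inputs = ests)
  class(out) <- c("specificity_factor", class(out))
  out
}

#' @export
print.specificity_factor <- function(x, ...) {
  cat(sprintf(
    "<specificity_factor> SF = %.4g (%.0f%% CI %.4g to %.4g; %s)\n",
    x$ratio, 100 * x$level, x$ci_low, x$ci_high, x$method_label
  ))
  invisible(x)
}
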
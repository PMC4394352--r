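# Independent oracles used to check the analytical code paths.

# Numerical Michaelis-Menten time course: dS/dt = -kcat * E * S / (Km + S),
# integrated with deSolve. Used to bound the first-order approximation
# error of the integrated-rate-equation velocity at S0 << Km.
mm_timecourse <- function(kcat, km, enzyme, s0, times) {
  out <- deSolve::ode(
    y = c(S = s0),
    times = c(0, times),
    func = function(t, y, p) list(-kcat * enzyme * y[["S"]] / (km + y[["S"]])),
    parms = NULL,
    rtol = 1e-10, atol = 1e-12
  )
  tibble::tibble(time_min = out[-1, "time"], substrate_uM = out[-1, "S"])
}

# Parametric bootstrap of the ratio of two independent t-scaled
# estimates; the percentile interval is the oracle for Fieller limits.
boot_ratio_ci <- function(a, sa, dfa, b, sb, dfb, n = 1e5, level = 0.95,
                          seed = 7) {
  withr::with_seed(seed, {
    num <- a + sa * stats::rt(n, dfa)
    den <- b + sb * stats::rt(n, dfb)
    unname(stats::quantile(num / den,
                           c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

# One simulated slope estimate: point estimate normal around the truth,
# standard error estimated with the usual chi-squared sampling noise.
sim_slope_estimate <- function(true_slope, cv, dof) {
  se_true <- cv * true_slope
  list(
    slope = stats::rnorm(1, true_slope, se_true),
    stderr = se_true * sqrt(stats::rchisq(1, dof) / dof),
    dof = dof
  )
}
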
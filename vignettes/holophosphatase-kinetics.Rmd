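---
title: "Methods: kinetic analysis of holophosphatase dephosphorylation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic analysis of holophosphatase dephosphorylation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophos)
```

## The measurement problem

Phosphatase assays against phosphoprotein substrates are read out on
Phos-Tag gels: phosphorylated substrate and dephosphorylated product run
as separate bands in the same lane. Absolute band intensities are
uninformative (they depend on loading, staining and imaging), but the
*ratio* within a lane is not. `holophos` starts from that observable and
carries it through to the quantities a specificity study needs: rate
constants, initial velocities, slope ratios with confidence limits, a
wildtype-normalised specificity factor, effector EC50s, and cellular
substrate concentrations.

The package analyses intensity *tables*, not images; densitometry and
background subtraction are upstream responsibilities. Negative
intensities are rejected rather than clamped, because a clamp would
silently bias every downstream ratio.

## Ratiometric quantification

For a lane with net band intensities $I_P$ (phospho) and $I_0$
(dephospho), the fraction dephosphorylated is $I_0/(I_P+I_0)$, and the
known total substrate concentration is partitioned as
$[S]_t = (1-f)\,[S]_{tot}$, product $= f\,[S]_{tot}$. The partition is
exactly conservative, and the fraction is invariant to any per-lane
loading factor applied to both bands.

A numerical note on that invariance: when both intensities are scaled by
a factor that is exactly representable in binary floating point (any
power of two), the computed fraction is bit-identical — scaling then
commutes with rounding. An arbitrary real factor perturbs the *stored*
intensities themselves by up to half an ulp each, so agreement is to
rounding error (≤ ~1e-15 relative), not bitwise. The tests check both
regimes.

An optional total-intensity floor (`min_total_intensity`, default 0 =
disabled) excludes very weak lanes, whose ratios are noise-dominated;
zero-total lanes are always an error naming the lane.

## First-order kinetics and the initial velocity

Well below $K_m$, Michaelis–Menten kinetics reduce to a first-order
decay $[S]_t = [S]_0 e^{-kt}$ with $k = k_{cat}[E]/K_m$, so
$\ln([S]_0/[S]_t)$ is linear in time with slope $k$.
`fit_first_order()` fits that line by least squares, through the origin
by default: the $t=0$ point is identically zero *by construction*, so
it carries no information and the fit spends no degree of freedom on an
intercept (dof $= n-1$). A free-intercept mode (dof $= n-2$) is kept
for diagnostics — a nonzero intercept indicates a mis-specified $[S]_0$
or a lag. The natural log is used internally; a base-10 view is
provided for figure-style reporting, and every downstream estimand is a
slope *ratio*, which is base-invariant.

The initial velocity comes from the integrated rate equation,

$$V_i = \ln\!\frac{[S]_0}{[S]_f}\cdot\frac{[S]_0}{\Delta t\,[ENZ]},$$

the instantaneous substrate conversion per molecule of enzyme at
$t = 0$, in min$^{-1}$. On exact first-order data $V_i = k[S]_0/[ENZ]$
independent of $\Delta t$; the estimate is considered valid at less
than 25% substrate depletion and a classed warning flags anything
beyond. Negative velocities ($[S]_f > [S]_0$, possible with noisy weak
lanes) are reported with a warning, never clamped.

`velocity_vs_substrate()` regresses $V_i$ on $[S]_0$, through the
origin (sub-$K_m$, $V_i \to 0$ as $[S]_0 \to 0$). Its slope is
proportional to $k_{cat}/K_m$ of the enzyme–substrate pair and equals
$k/[ENZ]$ on exact data. $K_m$ and $V_{max}$ themselves are
deliberately *not* estimated: these holophosphatases cannot be
saturated by substrate in vitro, so only the specificity-constant-
proportional slope is identified. When the sub-$K_m$ assumption is
violated the through-origin slope *underestimates* $k_{cat}[E]/K_m$;
the tests document this against a numerical Michaelis–Menten
integrator rather than correcting for it.

Two velocity modes exist because time-course figures can be summarised
either from the single early time point (default `time_point = 5`
minutes, the point at which excess substrate remains) or from the full
log-decay regression; both are exposed, and on first-order data they
agree.

## Ratio statistics

The scientific claims are fold changes — actin stimulation of the
specific substrate, preference of the binary complex for a non-specific
substrate — i.e. ratios of two slope estimates. `slope_ratio()` uses
Fieller's theorem with a t quantile: the interval is the set of
$\theta$ for which $a - \theta b$ is not significantly different from
zero, which is exact under normality and naturally *asymmetric*, as
ratio intervals should be. Degenerate zero-variance inputs give a point
interval; when the denominator is not significantly nonzero the
construction yields no finite interval, and the result is flagged
`unbounded` rather than truncated.

Degrees of freedom: when both inputs share a dof, that common dof is
used — validated against a $10^5$-draw parametric bootstrap of the
ratio of two independent t-scaled estimates, which it matches to well
under 1% at both bounds. When dofs differ, Welch–Satterthwaite pooling
applies. The common-dof choice is mildly conservative (empirical
coverage near 96–97% at nominal 95% in the calibration simulations,
inside the package's 93–97% acceptance band).

The specificity factor for a mutant substrate,

$$SF = \frac{V_{TC}(mut)/V_{BC}(mut)}{V_{TC}(wt)/V_{BC}(wt)},$$

is exactly 1 for wildtype and invariant to any common rescaling of the
four velocities. Its interval uses a log-scale delta method: the
variance of $\log SF$ is the sum of the four squared coefficients of
variation, with a t quantile at Satterthwaite's effective dof of that
*sum* (four components of equal precision at dof 8 give an effective
dof near 32). Using the raw input dof here over-covers; Satterthwaite
restores ~95% empirical coverage, which the acceptance tests verify
over 1000 simulation rounds. The CI construction for these published
fold-change styles is not uniquely standard, so every output carries a
`method_label` (`fieller_t`, `log_delta_t`).

## G-actin dose–response

Activation is modelled as a hyperbola
$v(A) = v_0 + (v_{max}-v_0)\,A/(EC_{50}+A)$ — a Hill exponent of 1,
appropriate for single-site effector binding; the exponent can be
freed for diagnostics. Fitting is Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with deterministic starts ($v_0$ from the zero
dose, $v_{max}$ from the largest velocity, $EC_{50}$ from the dose
nearest half-range), so runs are reproducible without random restarts.
A flat response has no identifiable $EC_{50}$: it is reported as `NA`
with a `flat_response` flag, never as a number. At the highest actin
concentrations the stimulation can *decline* (actin polymerises over
the assay); since no mechanistic model for that is warranted, the
declining doses can be excluded via `exclude_above` and are listed on
the fit. Including them drags the apparent $EC_{50}$ down — the tests
pin that direction as a regression guard.

## Cellular substrate concentration

`fit_calibration()` fits the immunoblot standard curve (signal vs pmol
loaded) with a free intercept — blots have nonzero background; an
origin-constrained mode exists. Saturation detection is automated: the
largest standard is dropped while it falls more than 10% (relative)
below the line refit on the remaining standards, emulating the manual
choice of unsaturated lanes; at least 3 in-range standards are
required. `lane_to_moles()` inverts the line only inside the linear
range. Signals at the boundary are accepted; saturated signals are
rejected. `estimate_abundance()` applies this per lysate lane, divides
by each lane's cytosolic volume and reports mean ± SD per sample,
excluding (and counting) lanes above the linear range or below the
curve's background intercept.

Volume accounting uses a packed-cell-volume model: buoyant density
1.005 g/ml converts packed cell mass to volume where needed, 60% of the
packed volume is intracellular and half of that is cytosol, so the
cytosolic volume is 30% of the packed volume. Because pmol/µl *is* µM,
no unit constants enter. The alternative route from copy number,
$c = n/(N_A V_{cell} f_{cyt})$, gives 0.95 µM for $1.71\times10^4$
molecules in a 60-fl cell with half-cytosol — the cross-check the
package reproduces in milliseconds.

## The synthetic-data generators

`sim_config()` fixes the simulated study design; the generators are
pure functions of (config, seed) via `withr::with_seed`, so identical
configs give byte-identical tables and the caller's RNG stream is
untouched.

* `simulate_timecourse()`: exponential decay sampled at 3/5/12/25
  minutes (the assay grid), starting concentrations 0.5–3 µM, enzyme
  26 nM — the design of the substrate-titration experiments. Band
  intensities are the concentration-proportional split of an arbitrary
  intensity scale, multiplied by a *shared* per-lane lognormal loading
  factor (sigma `loading_cv`, default 0.10) and independent per-band
  lognormal measurement noise (sigma `noise_cv`, default 0.05).
  Lognormal noise is the natural choice for strictly positive gel
  signals, and sharing the loading factor between the two bands of a
  lane is what makes the ratiometric invariance meaningful rather than
  vacuous.
* `simulate_dose_response()`: the activation hyperbola (defaults
  $v_0 = 1$, $v_{max} = 10$ min$^{-1}$, $EC_{50} = 0.08$ µM — the
  sub-100-nM regime of actin activation) with optional multiplicative
  linear attenuation above a decline-onset dose.
* `simulate_blot()`: a linear standard curve (slope 1000 signal/pmol,
  intercept 50) with an optional hard saturation ceiling, plus lysate
  lanes carrying the mass implied by a true cytosolic concentration
  (default 1.13 µM) and each lane's packed cell volume.

What the generators deliberately do **not** emulate: Michaelis–Menten
saturation (available only as a test oracle via numerical integration),
actin polymerisation kinetics, spatial gel artefacts, or
antibody-affinity nonlinearity beyond the saturation ceiling. Passing
the recovery tests therefore demonstrates that the *estimators* are
correct and calibrated under the assay's idealised statistical model —
not that real gels are free of systematic error.

## Problem sizes and numerical choices

The calibration and recovery checks run at fixed sizes chosen to make
Monte Carlo error small relative to the bands being checked: 1000
replicates for rate-constant recovery (mean within 2% of truth,
per-replicate within 10% for ≥95%), 2000 rounds for Fieller coverage
(93–97% band; binomial SD ≈ 0.5%), 1000 rounds for SF coverage, 500
fits for the EC50 median, 200 round trips for the blot. The full suite
runs in well under a minute on a single core.

Other numerical choices: through-origin fits drop the exact anchor
point rather than double-counting it; `lm` is used for every linear
fit (its zero-residual warnings on noiseless fixtures are muffled —
noiseless input is a supported case, not an anomaly); ties in the EC50
start search resolve to the smallest positive dose; all rejection
paths raise classed conditions (`holophos_input_error`,
`holophos_schema_error`, `holophos_saturation_error`,
`holophos_fit_error`) so pipelines can distinguish bad data from bad
configuration.

## Orchestration

`run_pipeline()` executes simulate → quantify → kinetics → ratio /
dose-response / abundance as configured from a YAML file or list,
writes per-stage CSVs, a JSON result bundle and a log to a fresh run
directory, never mutates inputs, converts stage warnings into manifest
flags, and reports schema violations by file and column. An annotated
example configuration ships with the package:

```{r}
cat(readLines(system.file("extdata", "example_config.yaml",
                          package = "holophos")), sep = "\n")
```

## Known limitations

* Everything rests on the sub-$K_m$ assumption; the package flags
  depletion but cannot detect saturation from a single time course.
* The Fieller/log-delta interval constructions are defensible defaults,
  not the only choices; method labels travel with every output.
* The saturation detector assumes saturation affects the *largest*
  standards first; exotic non-monotone blots need manual lane
  selection.
* Synthetic data validate estimator calibration, not gel chemistry.

```{r example, eval = FALSE}
cfg <- sim_config(k = 0.05, seed = 1)
q <- quantify_lanes(simulate_timecourse(cfg))
plot_log_decay(q, fit_decay_rates(q))
```
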
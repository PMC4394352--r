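# holophos

Quantitative enzymology of substrate-specific dephosphorylation by
eIF2α holophosphatase complexes.

Protein phosphatase 1 (PP1) gains substrate specificity from regulatory
subunits: PPP1R15 targets it to phosphorylated eIF2α, and monomeric
G-actin joining the PPP1R15–PP1 binary complex (BC) forms the
substrate-selective ternary complex (TC). The assays that establish this
read out dephosphorylation on Phos-Tag gels, where phosphorylated and
dephosphorylated species run as separate bands. `holophos` is the
analysis layer for such experiments: it consumes per-lane band-intensity
tables and produces rate constants, initial velocities,
specificity-constant-proportional slopes, fold-change and
specificity-factor statistics with confidence limits, G-actin EC50
estimates and cellular substrate-concentration estimates — plus seeded
synthetic-data generators so the entire pipeline is testable without any
gel images.

## The model

Ratiometric quantification: for a lane with phospho- and dephospho-band
intensities `I_P` and `I_0`, the fraction dephosphorylated is
`I_0 / (I_P + I_0)` — invariant to lane loading — and partitions the
known total substrate concentration into remaining substrate `[S]_t` and
product.

Sub-Km, dephosphorylation is pseudo-first-order:
`[S]_t = [S]_0 e^{-kt}`, so `ln([S]_0/[S]_t)` is linear in time with
slope `k`. The initial velocity comes from the integrated rate
equation,

```
Vi = ln([S]_0 / [S]_f) · [S]_0 / (Δt · [ENZ])     (per minute)
```

valid at < 25% substrate depletion; a flag is raised beyond that. Across
starting concentrations well below Km, the through-origin slope of `Vi`
versus `[S]_0` is proportional to `kcat/Km` of the enzyme–substrate
pair. Ratios of such slopes are the estimands of interest:

* fold changes (e.g. actin stimulation of the BC) with 95% Fieller
  confidence limits;
* the specificity factor of a mutant substrate,
  `SF = [V_TC(mut)/V_BC(mut)] ÷ [V_TC(wt)/V_BC(wt)]`, with a log-scale
  delta-method interval (SF ≡ 1 for wildtype).

G-actin activation follows a hyperbola
`v(A) = v0 + (vmax − v0)·A/(EC50 + A)`; cellular substrate
concentration comes from an immunoblot standard curve (linear range with
saturation detection) and packed-cell-volume accounting (60%
intracellular, half of that cytosol), or directly from molecules per
cell.

## Worked example

```r
library(holophos)

# a simulated time-course experiment: k = 0.05/min, 26 nM enzyme,
# substrate 0.5-3 uM sampled at 3/5/12/25 min, 5% band noise
cfg   <- sim_config(k = 0.05, noise_cv = 0.05, loading_cv = 0.1, seed = 1)
lanes <- simulate_timecourse(cfg)
q     <- quantify_lanes(lanes)
fit_decay_rates(q)[, c("substrate_total_uM", "k_per_min", "std.error", "r.squared")]
#> # A tibble: 4 × 4
#>   substrate_total_uM k_per_min std.error r.squared
#>                <dbl>     <dbl>     <dbl>     <dbl>
#> 1                0.5    0.0495  0.00152      0.997
#> 2                1      0.0508  0.000452     1.00
#> 3                2      0.0528  0.00140      0.998
#> 4                3      0.0488  0.000137     1.00
```

The fitted rate constants recover the simulated 0.05/min within noise;
`r.squared` near 1 is the first-order signature. Velocities and the
kcat/Km-proportional slope:

```r
v <- compute_initial_velocities(q, time_point = 5)
velocity_vs_substrate(v)
#> <slope_estimate> slope = 1.88496 +/- 0.0434 per_min_per_uM (dof 3, n 4, R^2 0.9984, origin)
```

(truth: `k/[ENZ]` = 0.05/0.026 = 1.92 per min per µM). A molecules-per-
cell conversion:

```r
molecules_to_concentration(1.71e4, cell_volume_fl = 60, cytosol_fraction = 0.5)
#> [1] 0.9465073   # uM
```

`run_pipeline()` orchestrates all stages from a YAML config (see
`system.file("extdata", "example_config.yaml", package = "holophos")`)
and writes CSV/JSON results plus a log to a run directory.

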
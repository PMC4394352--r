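# Annotated pipeline configuration for holophos::run_pipeline().
# Every block is optional; each stage runs only when configured.

# Generate inputs instead of reading them. Arguments are those of
# sim_config(); omitted ones keep their defaults (times 3/5/12/25 min,
# substrate 0.5-3 uM, 26 nM enzyme, 5% band noise, 10% loading noise).
simulate:
  k: 0.05            # first-order rate constant, per minute
  enzyme_uM: 0.026   # binary-complex concentration
  noise_cv: 0.05     # lognormal sigma of per-band measurement noise
  loading_cv: 0.10   # lognormal sigma of the shared per-lane loading
  seed: 1

# To analyse real data instead, drop the simulate block and point at a
# lane CSV (columns: condition_label, replicate_id, time_min,
# substrate_total_uM, enzyme_uM, effector_uM, intensity_phospho,
# intensity_dephospho):
# lanes: path/to/lanes.csv

quantify:
  min_total_intensity: 0   # 0 disables the weak-lane floor

kinetics:
  time_point: 5            # minutes; lane used for initial velocities
  intercept: origin        # through-origin decay fits (default)

# Fold change between two conditions' velocity-vs-substrate slopes,
# with a Fieller 95% confidence interval:
# ratio:
#   numerator: ternary
#   denominator: binary

# G-actin dose-response (EC50). Either simulate from the block above or
# read a CSV with dose_uM and velocity columns.
dose_response:
  simulate: true
  # exclude_above: 2.0     # uM; drop declining high-dose points

# Cytosolic substrate concentration from a quantitative immunoblot.
abundance:
  simulate: true
  saturation_tol: 0.10     # relative shortfall that flags saturation
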
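# Example run configuration for `icas-hemoflow run --config ...` /
# read_run_config(). Omitted keys take the package defaults documented in
# ?run_config; `seed` is mandatory.
n: 55
seed: 1
geometry_mode: axisymmetric
population:
  stenosis_mean: 43.2
  stenosis_sd: 17.3
  stenosis_range: [10, 85]
  radius_mean: 0.0015
  psv_mean: 0.9
  male_p: 0.545
solver:
  axial_cells: 256
  radial_cells: 48
  convergence_tolerance: 1.0e-06
  reynolds_cap: 2000
  outlet:
    kind: reference_pressure
measurement:
  deficit_threshold: 0.02
  point_tolerance: 0.02
stats:
  cutoff_percent: 50
  alpha: 0.05
  posthoc: wilcoxon
verbosity: 1
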
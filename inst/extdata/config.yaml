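# Packaged pipeline configuration.
# The synthetic stated world is scaled down from the study it emulates
# (240 taxa instead of ~15,700) so the full pipeline runs in seconds on one
# CPU; group quotas are scaled accordingly.  The RF stage runs at
# ntree = 200 / 20 iterations here (the rf_rank() function defaults remain
# ntree = 1000 / 100 iterations).
seed: 1
classify:
  min_total: 100
  alpha: 0.05
  n_bac: 50
  n_arch: 20
segfit:
  grid_points: 201
  alpha: 0.05
  criterion: f_test
biomarker:
  diff_threshold: 0.001
  alpha: 0.05
rf:
  n_trees: 200
  iterations: 20
  folds: 10
  k_max: 10
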
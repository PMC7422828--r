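# Example run configuration. Any subset of keys may be given; everything
# omitted falls back to the package defaults (see default_run_config()).
# Angles in degrees, times in seconds, luminance in cd/m2.
seed: 7
eye: right
zest:
  termination_sd: 1.5
  min_presentations: 4
observer:
  fp_rate: 0.028
  fn_rate: 0.073
cohort:
  n_observers: 4
  n_runs: 2
session:
  catch_rate: 0.07
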
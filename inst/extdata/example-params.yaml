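# Example configuration for the telegraph generator and colony model.
# Load with read_params_file(system.file("extdata", "example-params.yaml",
#                                        package = "telonoise"))
telegraph:
  k_on: 0.5
  k_off: 0.5
  mu_on: 100
  mu_off: 5
  cv_intrinsic: 0.2
  sigma_extrinsic: 0.15
  cv_measurement: 0.05
  lock_mode: toggling
colony:
  n_colonies: 6
  cells_per_colony: 256
  generations: 8
  p_founder_on: 0.5
  p_switch_per_division: 0.01
  n_regions_per_colony: 2
seed: 1
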
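# Shared fixtures: unit parameters and the standard constant-time datasets.
kp_unit <- kinetic_parameters(V = 1, Km = 1)

ct_dataset <- function(f, grid = default_s0_grid(), params = kp_unit) {
  simulate_design(design_spec("constant_time", grid, f, params))
}

cc_dataset <- function(f, grid = default_s0_grid(), params = kp_unit) {
  simulate_design(design_spec("constant_conversion", grid, f, params))
}
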
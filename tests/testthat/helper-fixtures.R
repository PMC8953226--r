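# Shared fixtures: a reduced-length scenario for structural tests
# (full-length phases are exercised in the acceptance tests) and a
# noiseless variant.

test_scenario <- function(seed = 1, ds_cycles = 10, ...) {
  sre_scenario(seed = seed, rs_hours = 0.5, post_minutes = 18,
               ds_cycles = ds_cycles, ...)
}

noiseless_scenario <- function(seed = 1, ds_cycles = 10, ...) {
  test_scenario(seed = seed, ds_cycles = ds_cycles,
                noise = list(gas = 0, metabolite = 0, feed = 0,
                             biomass = 0), ...)
}

# default operating point shorthand
rp <- reactor_params()
kp <- kinetic_params()
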
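# shared fixtures: the reference parameter set and a small fast experiment
# design used by the inference unit tests (2 doses, 1 replicate each,
# hourly sampling over 20 h -> 84 data points instead of 4152)
p_ref <- pflswitch::default_params()

small_design <- function(noise_cv = 0, noise_floor = 0) {
  experiment_design(dox_levels = c(1, 100), replicates = c(1L, 1L),
                    duration = 1200, dt = 60,
                    noise_cv = noise_cv, noise_floor = noise_floor)
}

# random positive parameter draw around the reference set (log-uniform
# within +/- half a decade); used by property-style tests
random_params <- function(span = 0.5) {
  vals <- lapply(unclass(p_ref), function(v) v * 10^stats::runif(1, -span, span))
  do.call(circuit_params, vals)
}
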
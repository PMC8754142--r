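# Default pipeline configuration for run_pipeline() / read_config().
# Any field omitted here falls back to qnq_default_config().

seed: 1

# named overrides of qnq_params(); empty means package defaults
params: {}

# arguments of qnq_default_scenarios()
scenarios:
  include_short: true
  starvation_weeks: 6
  n_replicates: 5

# measurement-noise model (seed is taken from the top-level seed)
noise:
  sigma_add: 0.005          # OD
  sigma_mult: 0.01          # relative
  replicate_effect_sd: 0.25 # h of per-replicate lag jitter

# regrowth hours at which biomass is compared across culture types
analysis_times: [2, 10, 24]

# OD increment defining the end of the lag phase
lag_delta_od: 0.01
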
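# Default parameters of the Q/NQ starvation-regrowth model.
# Units: time in hours, biomass in cells per 200 ul well-equivalent,
# nutrients in cell-equivalents (yield = 1).

v_max: 0.4                 # 1/h, maximal per-capita division rate
k_m: 1.0e+06                 # cell-equivalents, Monod half-saturation
yield: 1                   # cells per cell-equivalent (fixed by units)

d_q: 2.0723521925e-04      # 1/h, Q death rate  (= -ln(0.87)/28 d)
d_nq: 5.2180921091e-03     # 1/h, NQ death rate (= -ln(0.03)/28 d)
tau: 1.0e-3                # 1/h, Q -> NQ transition during starvation

sigma_max: 0.1             # 1/h, max NQ -> Q differentiation near depletion
k_diff: 1.0e+06              # cell-equivalents, half-max differentiation level

epsilon: 0.5               # recycling efficiency (complex environment only)

lag_q0: 1.5                # h, Q lag at week 0
lag_q_slope: 0.016666666666666666   # h/week (1.5 h -> 1.6 h over 6 weeks)
lag_nq0: 2.2               # h, NQ lag at week 0
lag_nq_slope: 1.2          # h/week (2.2 h -> 9.4 h over 6 weeks)
lag_q_short: 1.5           # h, Q growth onset after 4-day starvation
lag_nq_short: 0.5          # h, NQ growth onset after 4-day starvation

wake_rate: 2               # 1/h, dormant -> active conversion after the lag
lag_gate: hard             # "hard" or "smooth"
gate_width: 0.1            # h, width of the smooth gate

fresh_resource: 3.2e+07      # cell-equivalents per well in fresh medium
residual_seed_frac: 0.02   # spent-medium recyclable seed / fresh_resource

freeze_survival_q: 0.4     # fraction of Q surviving freezing
freeze_survival_nq: 0.1    # fraction of NQ surviving freezing
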
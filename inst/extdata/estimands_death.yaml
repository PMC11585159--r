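# The death-strategy family: while-alive (two estimators), composite(0),
# hypothetical (two random structures); treatment-policy TD and PD.
- death_strategy: while_alive
  estimator: gee_independence
- death_strategy: while_alive
  estimator: lmm_survivor_averaged
  random_structure: intercept_slope
- death_strategy: composite
  composite_value: 0
  estimator: gee_independence
- death_strategy: hypothetical
  estimator: lmm_marginal
  random_structure: intercept
- death_strategy: hypothetical
  estimator: lmm_marginal
  random_structure: intercept_slope
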
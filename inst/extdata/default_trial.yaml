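# Default single-arm trial simulation: 876 patients, 3-week cycles,
# QoL rising from 54 to 67 by cycle 4, QoL-linked mortality, PD -> TD lag,
# administrative censoring beyond the 40-cycle analysis window.
n_patients: 876
max_cycle: 40
cycle_weeks: 3
baseline_mean: 54.0
baseline_sd: 25.0
plateau_mean: 67.0
rise_cycles: 4
residual_sd: 12.0
predeath_drop: 4.0
predeath_window: 5
death_hazard_base: -3.5
death_hazard_qol_coef: 0.03
pd_hazard: 0.05
td_lag_distribution:
  name: geometric
  prob: 0.3
  offset: 1
td_no_pd_prob: 0.05
td_decrement: 5.0
censor_cycle_distribution:
  name: uniform_int
  min: 41
  max: 60
missing_prob_base: 0.07
missing_prob_event_bump: 0.15
seed: 20260927
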
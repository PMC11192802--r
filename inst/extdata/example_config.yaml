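# Example pipeline configuration. Omitted keys fall back to package defaults;
# unknown keys are rejected by name.
seed: 1
cohort:
  n_infants: 24
  hours_per_infant: 12.7
  sample_interval_s: 1
detection:
  hypox_pct: 80
  hypox_min_s: 30
  recovery_min_s: 8
  hypox_time_mode: CUMULATIVE
controller:
  baseline_update_interval_s: 300
  trailing_window_s: 900
  approach_fraction: 0.5
  fio2_max_delta: 0.15
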
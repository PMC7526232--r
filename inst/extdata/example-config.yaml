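# Example pipeline configuration (see read_pipeline_config)
seed: 1
cohort:
  group_sizes: {normal: 9, wheeze_only: 5, crackles_pm_wheeze: 5, cf_clear: 6}
  quadrants: [left_upper, right_upper, left_lower, right_lower]
  exclusions_per_device: 4
  duration_s: 20
devices: [hifi, lofi]
events:
  snr_db: 20
  crackle_rate: 6
  wheeze_rate: 2
  wheeze_given_crackles: 0.5
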
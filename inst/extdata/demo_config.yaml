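# Demonstration pipeline configuration: two small groups, 12-h recordings.
seed: 1
duration_hours: 12
min_segments: 48
groups:
  - preset: nssi
    n_subjects: 8
  - preset: hc
    n_subjects: 8
artifacts:
  ectopic_rate: 0.005
  iid_noise_floor: 3
preprocess:
  hr_min: 30
  hr_max: 200
  detrend_lambda: 500
  segment_length: 300
  min_consecutive: 30
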
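# Example scenario: combined dietary + dermal exposure, 3 days, 60 kg adult.
name: combined_oral_dermal
days: 3
body_weight: 60
routes:
  oral:
    total_mg: 1.95
    ratios: [0.5, 0.8, 0.65]
    times: [8, 12, 18]
    duration_h: 0.5
  dermal:
    rate_mg_h: 0.68
solver:
  dt: 0.05
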
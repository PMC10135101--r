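n_subjects: 12
regimen_mix:
- dose_mg: 1200.0
  interval_h: 4.0
  'n': 8.0
- dose_mg: 1200.0
  interval_h: 6.0
  'n': 2.0
- dose_mg: 2400.0
  interval_h: 4.0
  'n': 2.0
n_lead_doses: 5
dropout: 0.0
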
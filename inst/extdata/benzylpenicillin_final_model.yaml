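n_compartments: 2
ref_weight_kg: 70.0
allometric_exponents:
  clearance: 0.75
  volume: 1.0
theta:
  CL: 23.1
  V1: 15.1
  Q: 11.1
  V2: 9.8
omega2:
  CL: 0.1764
  V1: 0.051076
  V2: 0.042025
sigma2:
  prop: 0.021
  add: 0.006
covariates:
- param: CL
  cov: creatinine
  ref: 70.0
  value: -0.916
  type: power
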
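{
  "model_kind": "C",
  "n_clones": 3,
  "alpha": [1, 1.05, 1.05],
  "delta": [0.95, 1, 1],
  "a": [2000000000, 100000000, 100000000],
  "d": [1, 1, 1],
  "theta_s": [2e-07, 2e-06, 4e-07],
  "theta_d": [10, 100, 100],
  "omega": [
    [1, 0.11, 0.66],
    [-1, 1, 6.3],
    [0, 0, 1]
  ],
  "nu2": 0,
  "nu3": 2e-09,
  "nu_q1": 0.8,
  "nu_c1": 0.0475,
  "theta_q1": 5,
  "switch_kind": "sigmoid",
  "c1": 100,
  "c2": 0,
  "state0": {
    "xs": [4.95e-07, 8e-11, 0],
    "xd": [49.5, 0.008, 0],
    "xq1": 4.95e-07
  },
  "notes": "three-clone patient-simulation coefficients (profile PP14, mutation-origin third clone)"
}
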
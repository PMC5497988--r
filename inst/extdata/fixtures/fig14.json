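{
  "model_kind": "C",
  "n_clones": 2,
  "alpha": [1, 1.01],
  "delta": [0.96, 1],
  "a": [120000000, 100000000],
  "d": [0.9, 1.2],
  "theta_s": [1e-08, 1.6e-06],
  "theta_d": [1000, 100],
  "omega": [
    [1, 0.2],
    [-0.025, 1]
  ],
  "nu2": 0,
  "nu3": 0,
  "nu_q1": 0.4,
  "nu_c1": 4.8,
  "theta_q1": 0.51,
  "switch_kind": "sigmoid",
  "c1": 100,
  "c2": 0,
  "state0": {
    "xs": [1.73e-07, 2e-09],
    "xd": [17.3, 0.045],
    "xq1": 1e-05
  },
  "notes": "reduced two-clone patient-simulation coefficients (profile PP15)"
}
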
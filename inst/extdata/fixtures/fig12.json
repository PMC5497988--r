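{
  "model_kind": "C",
  "n_clones": 3,
  "alpha": [1, 1.018, 1.06],
  "delta": [1, 1, 1],
  "a": [100000000, 100000000, 100000000],
  "d": [1, 1, 1],
  "theta_s": [3.03e-08, 9.68e-07, 3.33e-07],
  "theta_d": [1000, 100, 100],
  "omega": [
    [1, -0.03, 0.112],
    [0, 1, 2.097],
    [0, 0, 1]
  ],
  "nu2": 0,
  "nu3": 0,
  "nu_q1": 0.25,
  "nu_c1": 0,
  "switch_kind": "sigmoid",
  "c1": 100,
  "c2": 0,
  "state0": {
    "xs": [1.73e-07, 4.5e-10, 1e-16],
    "xd": [17.3, 0.045, 0],
    "xq1": 1.73e-07
  },
  "notes": "three-clone patient-simulation coefficients (profile PP15, hypothetical pre-existing third clone; deactivation off)"
}
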
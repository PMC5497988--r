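{
  "model_kind": "A",
  "n_clones": 3,
  "alpha": [1, 1, 1],
  "delta": [1, 0.8, 0.8],
  "a": [1000000, 1000000, 1000000],
  "d": [1, 1, 1],
  "theta_s": [100, 10, 100],
  "theta_d": 10000000000,
  "omega": [
    [1, 1, 1],
    [0.5, 1, 1],
    [1, 0.5, 1]
  ],
  "nu2": 0,
  "nu3": 0,
  "nu_q1": null,
  "nu_c1": null,
  "theta_q1": null,
  "switch_kind": "heaviside",
  "c1": 100,
  "c2": 0,
  "state0": {
    "xs": [100, 5, 1],
    "xd": [70000000, 0, 0]
  },
  "notes": "three-clone test-simulation coefficients, theta_s2 = 10 (clone-2/3 decay and asymmetric-competition variations applied)"
}
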
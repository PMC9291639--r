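{
  "label": "table4_scenario1",
  "rows": 2,
  "cols": 4,
  "tox_probs": [
    [0.01, 0.1, 0.4, 0.5],
    [0.05, 0.15, 0.45, 0.55]
  ],
  "targets": [
    [2, 2]
  ],
  "eff_params": [
    [0.5, 0, -1.5, -2.5],
    [-1.5, -2, -3.5, -4.5]
  ],
  "phi": 0.3,
  "psi": 0,
  "n": 60,
  "eff_family": {
    "name": "normal",
    "sd": 1
  }
}
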
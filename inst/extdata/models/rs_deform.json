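{
  "name": "RSdeform",
  "feature_names": ["R_std", "D_max", "D_std", "D_ratio"],
  "beta0": -1.098,
  "betas": [0.663, -1.086, -0.745, 2.395],
  "standardization": {
    "R_std": {"mean": 0, "sd": 1},
    "D_max": {"mean": 0, "sd": 1},
    "D_std": {"mean": 0, "sd": 1},
    "D_ratio": {"mean": 0, "sd": 1}
  },
  "vessel_class": "vein"
}
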
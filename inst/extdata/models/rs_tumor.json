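{
  "name": "RStumor",
  "feature_names": ["T_flat", "T_sphere"],
  "beta0": 1.526,
  "betas": [7.093, -9.826],
  "standardization": null,
  "vessel_class": null
}
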
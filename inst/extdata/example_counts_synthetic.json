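{
  "description": "Synthetic active-necrosis count table generated by generateNecrosisCounts()",
  "generator": "generateNecrosisCounts",
  "parameters": {
    "n0": 30.3,
    "r": 0.141,
    "period_days": 31,
    "onset_days": 31
  },
  "times_days": [31, 92, 184, 368, 552],
  "n_fields": 30,
  "noise": "poisson",
  "seed": 20240901
}
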
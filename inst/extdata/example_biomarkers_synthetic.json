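{
  "description": "Synthetic four-group CSF biomarker cohort generated by generateBiomarkerGroups()",
  "generator": "generateBiomarkerGroups",
  "groups": {
    "nc": {
      "name": "nc",
      "n": 19,
      "log_mean": 5.99146454710798,
      "log_sd": 0.5
    },
    "dc": {
      "name": "dc",
      "n": 11,
      "log_mean": 5.70971290082548,
      "log_sd": 0.5
    },
    "MCI": {
      "name": "MCI",
      "n": 21,
      "log_mean": 6.75855033726374,
      "log_sd": 0.5
    },
    "AD": {
      "name": "AD",
      "n": 56,
      "log_mean": 6.14038545175697,
      "log_sd": 0.5
    }
  },
  "seed": 20240902
}
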
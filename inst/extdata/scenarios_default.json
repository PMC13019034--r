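[
  {
    "name": "lden_high",
    "evidence": {
      "lden": "high"
    }
  },
  {
    "name": "sensitivity_high",
    "evidence": {
      "sensitivity": "high"
    }
  },
  {
    "name": "lden_high_sensitivity_low",
    "evidence": {
      "lden": "high",
      "sensitivity": "low"
    }
  },
  {
    "name": "lden_low_sensitivity_high",
    "evidence": {
      "lden": "low",
      "sensitivity": "high"
    }
  },
  {
    "name": "lden_high_sensitivity_high",
    "evidence": {
      "lden": "high",
      "sensitivity": "high"
    }
  }
]
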
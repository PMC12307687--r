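{
  "R1": {
    "kind": "hill_inhibited",
    "k": 1,
    "inhibitors": {
      "species": ["S3p", "S6p"],
      "a": [0.05, 1.5],
      "h": [2, 2]
    }
  },
  "R2": {
    "kind": "mass_action",
    "k": 1
  },
  "R3": {
    "kind": "mass_action",
    "k": 1
  },
  "R4": {
    "kind": "mass_action",
    "k": 1
  },
  "R5": {
    "kind": "hill_inhibited",
    "k": 1,
    "inhibitors": {
      "species": "S1p",
      "a": 2,
      "h": 2
    }
  },
  "R6": {
    "kind": "mass_action",
    "k": 1
  },
  "R7": {
    "kind": "hill_inhibited",
    "k": 1,
    "inhibitors": {
      "species": ["S3p", "S6p", "Np"],
      "a": [0.1, 0.3, 0.05],
      "h": [2, 2, 2]
    }
  },
  "R8": {
    "kind": "mass_action",
    "k": 1
  }
}
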
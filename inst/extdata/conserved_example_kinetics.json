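{
  "R1": {
    "kind": "constant",
    "k": 1
  },
  "R2": {
    "kind": "hill_inhibited",
    "k": 1,
    "inhibitors": {
      "species": "C",
      "a": 0.5,
      "h": 1
    }
  },
  "R3": {
    "kind": "hill_inhibited",
    "k": 1,
    "inhibitors": {
      "species": "E",
      "a": 0.8,
      "h": 1
    }
  },
  "R4": {
    "kind": "mass_action",
    "k": 1
  },
  "R5": {
    "kind": "mass_action",
    "k": 1
  },
  "R6": {
    "kind": "mass_action",
    "k": 0.7
  }
}
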
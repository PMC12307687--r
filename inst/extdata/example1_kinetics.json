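{
  "R1": {
    "kind": "constant",
    "k": 1
  },
  "R2": {
    "kind": "sigmoid_activated",
    "k": 2,
    "activator": "B",
    "theta": 1,
    "tau": 0.3,
    "eps": 0
  },
  "R3": {
    "kind": "mass_action",
    "k": 1
  },
  "R4": {
    "kind": "mass_action",
    "k": 1
  }
}
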
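{
  "species": [
    {
      "id": "A",
      "name": "A"
    },
    {
      "id": "B",
      "name": "B"
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "reactants": [],
      "products": {
        "A": 1
      },
      "regulators": []
    },
    {
      "id": "R2",
      "reactants": {
        "A": 1
      },
      "products": {
        "B": 1
      },
      "regulators": {
        "B": "+"
      }
    },
    {
      "id": "R3",
      "reactants": {
        "B": 1
      },
      "products": {
        "A": 1
      },
      "regulators": []
    },
    {
      "id": "R4",
      "reactants": {
        "A": 1
      },
      "products": [],
      "regulators": []
    }
  ],
  "metadata": {
    "fixture": "example1"
  }
}
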
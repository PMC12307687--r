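{
  "species": [
    {
      "id": "A",
      "name": "A"
    },
    {
      "id": "B",
      "name": "B"
    },
    {
      "id": "C",
      "name": "C"
    },
    {
      "id": "D",
      "name": "D"
    },
    {
      "id": "E",
      "name": "E"
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
        "C": "-"
      }
    },
    {
      "id": "R3",
      "reactants": {
        "B": 1
      },
      "products": {
        "C": 1
      },
      "regulators": {
        "E": "-"
      }
    },
    {
      "id": "R4",
      "reactants": {
        "C": 1
      },
      "products": [],
      "regulators": []
    },
    {
      "id": "R5",
      "reactants": {
        "D": 1,
        "E": 1
      },
      "products": {
        "B": 1
      },
      "regulators": []
    },
    {
      "id": "R6",
      "reactants": {
        "B": 1
      },
      "products": {
        "D": 1,
        "E": 1
      },
      "regulators": []
    }
  ],
  "metadata": {
    "fixture": "conserved_example"
  }
}
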
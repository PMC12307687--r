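{
  "species": [
    {
      "id": "S1",
      "name": "STAT1"
    },
    {
      "id": "S1p",
      "name": "STAT1+"
    },
    {
      "id": "S3",
      "name": "STAT3"
    },
    {
      "id": "S3p",
      "name": "STAT3+"
    },
    {
      "id": "S6",
      "name": "STAT6"
    },
    {
      "id": "S6p",
      "name": "STAT6+"
    },
    {
      "id": "N",
      "name": "NFkB"
    },
    {
      "id": "Np",
      "name": "NFkB+"
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "reactants": {
        "S1": 1
      },
      "products": {
        "S1p": 1
      },
      "regulators": {
        "S3p": "-",
        "S6p": "-"
      }
    },
    {
      "id": "R2",
      "reactants": {
        "S1p": 1
      },
      "products": {
        "S1": 1
      },
      "regulators": []
    },
    {
      "id": "R3",
      "reactants": {
        "S3": 1
      },
      "products": {
        "S3p": 1
      },
      "regulators": []
    },
    {
      "id": "R4",
      "reactants": {
        "S3p": 1
      },
      "products": {
        "S3": 1
      },
      "regulators": []
    },
    {
      "id": "R5",
      "reactants": {
        "S6": 1
      },
      "products": {
        "S6p": 1
      },
      "regulators": {
        "S1p": "-"
      }
    },
    {
      "id": "R6",
      "reactants": {
        "S6p": 1
      },
      "products": {
        "S6": 1
      },
      "regulators": []
    },
    {
      "id": "R7",
      "reactants": {
        "N": 1
      },
      "products": {
        "Np": 1
      },
      "regulators": {
        "S3p": "-",
        "Np": "-"
      }
    },
    {
      "id": "R8",
      "reactants": {
        "Np": 1
      },
      "products": {
        "N": 1
      },
      "regulators": []
    }
  ],
  "metadata": {
    "fixture": "macrophage_socs3d_klf4d"
  }
}
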
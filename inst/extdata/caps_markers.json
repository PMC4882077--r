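[
  {
    "locus": "PRS016",
    "enzyme": {
      "name": "SalI",
      "recognition": "GTCGAC",
      "cut_top": -5,
      "cut_bottom": -1
    },
    "alleles": {
      "1": {
        "length": 700,
        "cuts": 481
      },
      "2": {
        "length": 700,
        "cuts": [271, 481]
      }
    }
  },
  {
    "locus": "PRS049",
    "enzyme": {
      "name": "KpnI",
      "recognition": "GGTACC",
      "cut_top": -1,
      "cut_bottom": -5
    },
    "alleles": {
      "1": {
        "length": 479,
        "cuts": []
      },
      "2": {
        "length": 479,
        "cuts": 292
      }
    }
  },
  {
    "locus": "PRS088",
    "enzyme": {
      "name": "AvaII",
      "recognition": "GGWCC",
      "cut_top": -4,
      "cut_bottom": -1
    },
    "alleles": {
      "1": {
        "length": 757,
        "cuts": []
      },
      "2": {
        "length": 757,
        "cuts": 449
      }
    }
  },
  {
    "locus": "ITS",
    "enzyme": {
      "MboII": {
        "name": "MboII",
        "recognition": "GAAGA",
        "cut_top": 8,
        "cut_bottom": 7
      },
      "FokI": {
        "name": "FokI",
        "recognition": "GGATG",
        "cut_top": 9,
        "cut_bottom": 13
      }
    },
    "alleles": {
      "A": {
        "length": 773,
        "cuts": {
          "MboII": 396,
          "FokI": []
        }
      },
      "B": {
        "length": 772,
        "cuts": {
          "MboII": [],
          "FokI": 209
        }
      },
      "C": {
        "length": 771,
        "cuts": {
          "MboII": [395, 659],
          "FokI": 209
        }
      }
    }
  }
]
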
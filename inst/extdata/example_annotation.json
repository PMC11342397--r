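{
  "schema": "fabdyn-annotation/1",
  "chains": {
    "LC1": "A",
    "LC2": "B",
    "HC1": "C",
    "HC2": "D"
  },
  "domains": {
    "HC1": {
      "VH": [1, 8],
      "CH1": [9, 16],
      "hinge": [17, 21],
      "CH2": [22, 29],
      "CH3": [30, 37]
    },
    "HC2": {
      "VH": [1, 8],
      "CH1": [9, 16],
      "hinge": [17, 21],
      "CH2": [22, 29],
      "CH3": [30, 37]
    },
    "LC1": {
      "VL": [1, 8],
      "CL": [9, 16]
    },
    "LC2": {
      "VL": [1, 8],
      "CL": [9, 16]
    }
  },
  "glycans": {
    "fc_glycan_1": {
      "chain": "E"
    },
    "fc_glycan_2": {
      "chain": "F"
    }
  },
  "residue_sets": {
    "hinge": {
      "HC1": {
        "chain": "HC1",
        "resid": [17, 18, 19, 20, 21]
      },
      "HC2": {
        "chain": "HC2",
        "resid": [17, 18, 19, 20, 21]
      }
    },
    "fcgr3a_site": {
      "HC1": {
        "chain": "HC1",
        "resid": [22, 23, 24]
      },
      "HC2": {
        "chain": "HC2",
        "resid": [22, 23, 24]
      }
    },
    "fcrn_site": {
      "HC1": {
        "chain": "HC1",
        "resid": [30, 31, 32]
      },
      "HC2": {
        "chain": "HC2",
        "resid": [30, 31, 32]
      }
    }
  },
  "anchors": {
    "val34_hc1": {
      "chain": "HC1",
      "resid": 8,
      "atom": "CA"
    },
    "val34_hc2": {
      "chain": "HC2",
      "resid": 8,
      "atom": "CA"
    },
    "cys228_sg": {
      "chain": "HC1",
      "resid": 19,
      "atom": "SG"
    },
    "asn299_hc1": {
      "chain": "HC1",
      "resid": 25,
      "atom": "CA"
    },
    "asn299_hc2": {
      "chain": "HC2",
      "resid": 25,
      "atom": "CA"
    }
  }
}
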
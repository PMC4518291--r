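{
  "PhGlp_syn": {
    "subfamily": "Glp",
    "npa1_pos": 97,
    "npa2_pos": 213,
    "arR_positions": {
      "TMD2_aromatic": 77,
      "TMD5": 201,
      "LE1": 210,
      "LE2": 216
    },
    "tmd5_aa": "G"
  },
  "BgAqp_syn": {
    "subfamily": "Prip",
    "npa1_pos": 93,
    "npa2_pos": 209,
    "arR_positions": {
      "TMD2_aromatic": 73,
      "TMD5": 197,
      "LE1": 206,
      "LE2": 212
    },
    "tmd5_aa": "H"
  },
  "DmDrip_syn": {
    "subfamily": "Drip",
    "npa1_pos": 97,
    "npa2_pos": 213,
    "arR_positions": {
      "TMD2_aromatic": 77,
      "TMD5": 201,
      "LE1": 210,
      "LE2": 216
    },
    "tmd5_aa": "H"
  },
  "PvAqp2_syn": {
    "subfamily": "Eglp",
    "npa1_pos": 70,
    "npa2_pos": 186,
    "arR_positions": {
      "TMD2_aromatic": 50,
      "TMD5": 174,
      "LE1": 183,
      "LE2": 189
    },
    "tmd5_aa": "A"
  },
  "DmBib_syn": {
    "subfamily": "Bib",
    "npa1_pos": 97,
    "npa2_pos": 213,
    "arR_positions": {
      "TMD2_aromatic": 77,
      "TMD5": 201,
      "LE1": 210,
      "LE2": 216
    },
    "tmd5_aa": "E"
  },
  "HsAqp12L_syn": {
    "subfamily": "Aqp12like",
    "npa1_pos": 97,
    "npa2_pos": 213,
    "arR_positions": {
      "TMD2_aromatic": 77,
      "TMD5": 201,
      "LE1": 210,
      "LE2": 216
    },
    "tmd5_aa": "C"
  }
}
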
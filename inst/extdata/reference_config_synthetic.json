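{
  "tir": {
    "id": "AtTIR1_synthetic",
    "fbox": [10, 55],
    "lrr": [60, 585],
    "pocket": {
      "pos": [410, 440, 441, 464, 465, 405, 438, 439, 440, 462, 489],
      "aa": ["K", "S", "G", "A", "F", "C", "S", "L", "S", "S", "R"],
      "role": ["orientation", "orientation", "orientation", "orientation", "orientation", "selectivity", "selectivity", "selectivity", "selectivity", "selectivity", "selectivity"]
    },
    "ac": {
      "pos": [530, 545, 566],
      "aa": ["N", "R", "D"],
      "role": ["ac_critical", "ac_critical", "ac_critical"]
    }
  },
  "arf": {
    "id": "ArfRef_synthetic",
    "dbd": [30, 330],
    "dd": [240, 330],
    "pb1": [560, 650],
    "pb1_k": 580,
    "opca": [625, 629]
  }
}
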
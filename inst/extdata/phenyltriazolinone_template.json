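{
  "scaffold": [
    {
      "element": "N",
      "x": 1.19091113169286,
      "y": 0
    },
    {
      "element": "N",
      "x": 0.368011778483394,
      "y": 1.13262379212493
    },
    {
      "element": "C",
      "x": -0.963467344329821,
      "y": 0.7
    },
    {
      "element": "N",
      "x": -0.963467344329822,
      "y": -0.7
    },
    {
      "element": "C",
      "x": 0.368011778483393,
      "y": -1.13262379212493
    },
    {
      "element": "O",
      "x": 0.745012511620829,
      "y": -2.29291274200501
    },
    {
      "element": "C",
      "x": -2.15272232606099,
      "y": -1.56404432086994
    },
    {
      "element": "H",
      "x": -3.03455084992969,
      "y": -2.20473024586873
    },
    {
      "element": "H",
      "x": -1.15695777723056,
      "y": -2.00738726182256
    },
    {
      "element": "H",
      "x": -2.26665835102274,
      "y": -0.480015454918518
    },
    {
      "element": "C",
      "x": 2.59091113169286,
      "y": 0
    },
    {
      "element": "C",
      "x": 3.29091113169286,
      "y": 1.21243556529821
    },
    {
      "element": "C",
      "x": 4.69091113169286,
      "y": 1.21243556529821
    },
    {
      "element": "C",
      "x": 5.39091113169285,
      "y": 0
    },
    {
      "element": "C",
      "x": 4.69091113169286,
      "y": -1.21243556529821
    },
    {
      "element": "C",
      "x": 3.29091113169285,
      "y": -1.21243556529821
    },
    {
      "element": "H",
      "x": 2.74591113169286,
      "y": 2.15640325542325
    },
    {
      "element": "H",
      "x": 5.23591113169286,
      "y": 2.15640325542325
    },
    {
      "element": "H",
      "x": 5.23591113169286,
      "y": -2.15640325542325
    },
    {
      "element": "H",
      "x": 2.74591113169285,
      "y": -2.15640325542325
    },
    {
      "element": "C",
      "x": -2.17699283589224,
      "y": 1.58167787843871
    },
    {
      "element": "H",
      "x": -2.81767876089104,
      "y": 0.699849354570017
    },
    {
      "element": "H",
      "x": -1.53630691089345,
      "y": 2.4635064023074
    },
    {
      "element": "C",
      "x": -3.39051832745466,
      "y": 2.46335575687742
    },
    {
      "element": "C",
      "x": -5.54489680347734,
      "y": 3.16335575687742
    },
    {
      "element": "C",
      "x": -4.72199745026788,
      "y": 2.03073196475249
    },
    {
      "element": "H",
      "x": -6.63489680347734,
      "y": 3.16335575687742
    }
  ],
  "bonds": [
    {
      "i": 1,
      "j": 2,
      "order": 1
    },
    {
      "i": 2,
      "j": 3,
      "order": 2
    },
    {
      "i": 3,
      "j": 4,
      "order": 1
    },
    {
      "i": 4,
      "j": 5,
      "order": 1
    },
    {
      "i": 5,
      "j": 1,
      "order": 1
    },
    {
      "i": 5,
      "j": 6,
      "order": 2
    },
    {
      "i": 4,
      "j": 7,
      "order": 1
    },
    {
      "i": 7,
      "j": 8,
      "order": 1
    },
    {
      "i": 7,
      "j": 9,
      "order": 1
    },
    {
      "i": 7,
      "j": 10,
      "order": 1
    },
    {
      "i": 1,
      "j": 11,
      "order": 1
    },
    {
      "i": 11,
      "j": 12,
      "order": 2
    },
    {
      "i": 12,
      "j": 13,
      "order": 1
    },
    {
      "i": 13,
      "j": 14,
      "order": 2
    },
    {
      "i": 14,
      "j": 15,
      "order": 1
    },
    {
      "i": 15,
      "j": 16,
      "order": 2
    },
    {
      "i": 16,
      "j": 11,
      "order": 1
    },
    {
      "i": 12,
      "j": 17,
      "order": 1
    },
    {
      "i": 13,
      "j": 18,
      "order": 1
    },
    {
      "i": 15,
      "j": 19,
      "order": 1
    },
    {
      "i": 16,
      "j": 20,
      "order": 1
    },
    {
      "i": 3,
      "j": 21,
      "order": 1
    },
    {
      "i": 21,
      "j": 22,
      "order": 1
    },
    {
      "i": 21,
      "j": 23,
      "order": 1
    },
    {
      "i": 21,
      "j": 24,
      "order": 1
    },
    {
      "i": 25,
      "j": 27,
      "order": 1
    }
  ],
  "slots": {
    "X": {
      "type": "ring_atom",
      "pos": [-3.39051832745466, 3.86335575687742],
      "out_angle": 36,
      "neighbors": [24, null],
      "codes": ["S", "O", "CH", "C"]
    },
    "Y": {
      "type": "ring_atom",
      "pos": [-4.72199745026788, 4.29597954900235],
      "out_angle": 108,
      "neighbors": [25, null],
      "codes": ["CH", "S", "C"]
    },
    "R1": {
      "type": "substituent",
      "parent": 14,
      "pos": [5.39091113169285, 0],
      "out_angle": 0,
      "codes": ["H", "Cl", "CH3", "CF3", "Br", "F"]
    },
    "R2_3": {
      "type": "substituent",
      "parent": 26,
      "pos": [-4.72199745026788, 2.03073196475249],
      "out_angle": 252,
      "codes": ["H", "CH3", "Br"]
    },
    "R2_5": {
      "type": "on_Y",
      "out_angle": 108,
      "codes": ["H", "CH3"]
    }
  }
}
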
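[
  {
    "id": "amide",
    "priority": 10,
    "atoms": [
      {"elem": "*"},
      {"elem": "C", "aromatic": false, "neighbor": {"elem": "O", "order": 2}},
      {"elem": "N", "aromatic": false},
      {"elem": "*"}
    ],
    "bond_order": 1,
    "boundaries": [-90, 90]
  },
  {
    "id": "aromatic-aromatic",
    "priority": 20,
    "atoms": [
      {"elem": "*"},
      {"aromatic": true},
      {"aromatic": true},
      {"elem": "*"}
    ],
    "bond_order": 1,
    "boundaries": [-45, 45],
    "period": 180
  },
  {
    "id": "conjugated",
    "priority": 30,
    "atoms": [
      {"elem": "*"},
      {"aromatic": false, "neighbor": {"order": 2}},
      {"aromatic": false, "neighbor": {"order": 2}},
      {"elem": "*"}
    ],
    "bond_order": 1,
    "boundaries": [-90, 90]
  },
  {
    "id": "sp3-aromatic",
    "priority": 40,
    "atoms": [
      {"elem": "*"},
      {"elem": "C", "aromatic": false},
      {"aromatic": true},
      {"elem": "*"}
    ],
    "bond_order": 1,
    "boundaries": [-45, 45],
    "period": 180
  },
  {
    "id": "sp3-sp3",
    "priority": 50,
    "atoms": [
      {"elem": "*"},
      {"elem": "C", "aromatic": false},
      {"elem": "C", "aromatic": false},
      {"elem": "*"}
    ],
    "bond_order": 1,
    "boundaries": [-120, 0, 120]
  },
  {
    "id": "generic",
    "priority": 99,
    "atoms": [
      {"elem": "*"},
      {"elem": "*"},
      {"elem": "*"},
      {"elem": "*"}
    ],
    "boundaries": [-120, 0, 120]
  }
]
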
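{
  "name": "brain",
  "regions": [
    "AC",
    "PC",
    "IC",
    "HG",
    "FOrb",
    "Hippo",
    "Hypo",
    "Amyg",
    "Thal",
    "NAcc",
    "VTA",
    "PAG",
    "PBN",
    "LC"
  ],
  "edges": [
    [
      "AC",
      "PC"
    ],
    [
      "AC",
      "IC"
    ],
    [
      "AC",
      "FOrb"
    ],
    [
      "AC",
      "Amyg"
    ],
    [
      "PC",
      "AC"
    ],
    [
      "IC",
      "AC"
    ],
    [
      "IC",
      "HG"
    ],
    [
      "Hypo",
      "Thal"
    ],
    [
      "Hypo",
      "VTA"
    ],
    [
      "Hypo",
      "PAG"
    ],
    [
      "Amyg",
      "Hippo"
    ],
    [
      "Amyg",
      "Thal"
    ],
    [
      "Thal",
      "AC"
    ],
    [
      "Thal",
      "PC"
    ],
    [
      "Thal",
      "Hippo"
    ],
    [
      "Thal",
      "Hypo"
    ],
    [
      "VTA",
      "NAcc"
    ],
    [
      "PBN",
      "Thal"
    ],
    [
      "LC",
      "Thal"
    ],
    [
      "LC",
      "PBN"
    ]
  ],
  "latents": [
    {
      "name": "Lat0",
      "target": "FOrb"
    },
    {
      "name": "Lat1",
      "target": "IC"
    },
    {
      "name": "Lat2",
      "target": "LC"
    }
  ]
}
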
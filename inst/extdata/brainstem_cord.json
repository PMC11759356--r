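{
  "name": "brainstem_cord",
  "regions": [
    "Thal",
    "Hypo",
    "PAG",
    "LC",
    "PBN",
    "NTS",
    "NGc",
    "NRM",
    "DRt",
    "C6RD"
  ],
  "edges": [
    [
      "Thal",
      "Hypo"
    ],
    [
      "Hypo",
      "Thal"
    ],
    [
      "Hypo",
      "PAG"
    ],
    [
      "Hypo",
      "NTS"
    ],
    [
      "PAG",
      "NGc"
    ],
    [
      "PAG",
      "NRM"
    ],
    [
      "LC",
      "Thal"
    ],
    [
      "LC",
      "PBN"
    ],
    [
      "PBN",
      "Thal"
    ],
    [
      "NGc",
      "C6RD"
    ],
    [
      "NRM",
      "C6RD"
    ],
    [
      "DRt",
      "C6RD"
    ],
    [
      "C6RD",
      "DRt"
    ]
  ],
  "latents": [
    {
      "name": "Lat2",
      "target": "LC"
    }
  ]
}
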
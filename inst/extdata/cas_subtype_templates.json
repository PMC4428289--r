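[
  {
    "subtype_id": "I-A",
    "core": ["cas6", "cas3", "cas8a", "cas7", "cas5"],
    "optional": ["cas1", "cas2"]
  },
  {
    "subtype_id": "I-D",
    "core": ["cas3", "csc3", "csc2", "csc1", "cas6", "cas4"],
    "optional": ["cas1", "cas2"]
  },
  {
    "subtype_id": "III-A",
    "core": ["cas10", "csm3", "csm4", "csm5", "csm6", "cas6"],
    "optional": ["cas1", "cas2"]
  },
  {
    "subtype_id": "III-B",
    "core": ["cas10", "cmr3", "cmr4", "cmr6"],
    "optional": ["cas1", "cas2"]
  }
]
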
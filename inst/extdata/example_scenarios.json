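[
  {"name": "protective", "ps": 24, "peep": 10, "vt": 0.38, "f": 22, "pt": 25},
  {"name": "moderate",   "ps": 27, "peep": 8,  "vt": 0.45, "f": 18, "pt": 23},
  {"name": "high_drive", "ps": 32, "peep": 6,  "vt": 0.6,  "f": 16, "pt": 21}
]
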
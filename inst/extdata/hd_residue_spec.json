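[
  {"column": 19, "allowed": ["E"], "note": "glutamic acid, alpha-helix 1"},
  {"column": 31, "allowed": ["R"], "note": "arginine, alpha-helix 2"},
  {"column": 33, "allowed": ["E"], "note": "glutamic acid, alpha-helix 2"},
  {"column": 54, "allowed": ["M"], "note": "methionine, alpha-helix 3"}
]
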
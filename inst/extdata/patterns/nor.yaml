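# Error-pattern rule tables for Norwegian.
language: "nor"
fronting:
  map: {"k": "t", "g": "d", "N": "n"}
backing:
  map: {"t": "k", "d": "g", "n": "N", "t'": "k", "d'": "g", "n'": "N"}
stopping:
  map: {"f": "p", "v": "b", "s": "t", "C": "t", "s'": "t'"}
  before_plosive: "delete"
r_weakening:
  rhotics: ["r", "r'"]
  target: "j"
weak_syllable_deletion:
  anchors: ["primary", "accent2"]
cluster_reduction:
  keep_ccc: 2
  s_onsets: ["s", "s'"]
  exceptions: {}
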
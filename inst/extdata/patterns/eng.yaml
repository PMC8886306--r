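# Error-pattern rule tables for English.
language: "eng"
fronting:
  map: {"k": "t", "g": "d", "N": "n"}
backing:
  map: {"t": "k", "d": "g", "n": "N"}
stopping:
  map: {"f": "p", "v": "b", "s": "t", "T": "t", "S": "t", "tS": "t",
        "D": "d", "z": "d", "Z": "d", "dZ": "d"}
  before_plosive: "delete"
r_weakening:
  rhotics: ["r"]
  target: "j"
weak_syllable_deletion:
  anchors: ["primary", "accent2"]
cluster_reduction:
  keep_ccc: 2
  s_onsets: ["s"]
  # English /sl/ keeps the /s/ (unlike Swedish/Norwegian)
  exceptions: {"sl": 1}
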
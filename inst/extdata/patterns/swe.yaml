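# Error-pattern rule tables for Swedish.
# All symbols must exist in the Swedish inventory.
language: "swe"
fronting:
  map: {"k": "t", "g": "d", "N": "n"}
backing:
  map: {"t": "k", "d": "g", "n": "N", "t'": "k", "d'": "g", "n'": "N"}
stopping:
  map: {"f": "p", "v": "b", "s": "t", "C": "t", "s'": "t'", "x": "k"}
  # a mapped fricative directly before a plosive in the same cluster is
  # deleted instead of substituted ("delete" | "substitute_anyway")
  before_plosive: "delete"
r_weakening:
  rhotics: ["r"]
  target: "j"
weak_syllable_deletion:
  anchors: ["primary", "accent2"]
cluster_reduction:
  # onsets of length >= 3 keep the member at this position:
  keep_ccc: 2
  # two-member onsets starting with one of these keep the second member:
  s_onsets: ["s", "s'"]
  # cluster-specific overrides (onset symbols pasted together -> kept position)
  exceptions: {}
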
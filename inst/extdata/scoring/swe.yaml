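# Metric scoring configuration for Swedish.
#
# IPC: additive points for singleton (non-cluster) fricatives/affricates,
# dorsal consonants, consonant clusters, and a bonus for heterorganic
# clusters. Symbols under "excluded" (the rhotic and the glide) earn no
# points and do not contribute a place of articulation when deciding
# whether a cluster is heterorganic.
#
# WCM: Stoel-Gammon word patterns (>= 3 syllables; non-initial primary
# stress/accent), syllable structures (word-final consonant; per
# cluster) and sound classes (velar; liquid; fricative/affricate, with
# an extra point when voiced). In Swedish /j/ is a voiced fricative and
# therefore scores 2; /r/ scores 1 as a liquid.
language: "swe"
ipc:
  points:
    singleton_fricative: 1
    dorsal: 1
    cluster: 1
    heterorganic: 1
  excluded: ["r", "j"]
wcm:
  points:
    long_word: 1
    noninitial_stress: 1
    final_consonant: 1
    cluster: 1
    velar: 1
    liquid: 1
    fricative: 1
    voiced_fricative: 1
  velar_symbols: ["k", "g", "N", "x"]
  liquid_manners: ["liquid", "tap"]
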
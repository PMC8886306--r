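# Metric scoring configuration for English. /j/ is an approximant and
# earns no WCM sound-class points (so /r/ -> /j/ lowers complexity,
# opposite to Swedish/Norwegian where /j/ is a voiced fricative).
language: "eng"
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
  velar_symbols: ["k", "g", "N"]
  liquid_manners: ["liquid"]
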
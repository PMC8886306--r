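# Swedish phoneme inventory (SAMPA-style ASCII symbols).
# Retroflexes carry a trailing apostrophe (t' d' n' l' s'); the
# dorso-velar fricative (IPA open-o "sje" sound) is written "x";
# the alveolo-palatal fricative (IPA curly-c "tje" sound) is "C".
# /j/ is classified as a voiced (palatal) fricative in Swedish.
language: "swe"
name: "Swedish"
markers:
  primary: "\""
  accent2: "\"\""
  secondary: "%"
  syllable: "$"
  length: ":"
consonants:
  - {symbol: "p",  place: "labial",    manner: "plosive",   voiced: false}
  - {symbol: "b",  place: "labial",    manner: "plosive",   voiced: true}
  - {symbol: "t",  place: "coronal",   manner: "plosive",   voiced: false}
  - {symbol: "d",  place: "coronal",   manner: "plosive",   voiced: true}
  - {symbol: "t'", place: "retroflex", manner: "plosive",   voiced: false}
  - {symbol: "d'", place: "retroflex", manner: "plosive",   voiced: true}
  - {symbol: "k",  place: "dorsal",    manner: "plosive",   voiced: false}
  - {symbol: "g",  place: "dorsal",    manner: "plosive",   voiced: true}
  - {symbol: "f",  place: "labial",    manner: "fricative", voiced: false}
  - {symbol: "v",  place: "labial",    manner: "fricative", voiced: true}
  - {symbol: "s",  place: "coronal",   manner: "fricative", voiced: false}
  - {symbol: "s'", place: "retroflex", manner: "fricative", voiced: false}
  - {symbol: "C",  place: "coronal",   manner: "fricative", voiced: false}
  - {symbol: "x",  place: "dorsal",    manner: "fricative", voiced: false}
  - {symbol: "h",  place: "glottal",   manner: "fricative", voiced: false}
  - {symbol: "j",  place: "dorsal",    manner: "fricative", voiced: true}
  - {symbol: "m",  place: "labial",    manner: "nasal",     voiced: true}
  - {symbol: "n",  place: "coronal",   manner: "nasal",     voiced: true}
  - {symbol: "n'", place: "retroflex", manner: "nasal",     voiced: true}
  - {symbol: "N",  place: "dorsal",    manner: "nasal",     voiced: true}
  - {symbol: "l",  place: "coronal",   manner: "liquid",    voiced: true}
  - {symbol: "l'", place: "retroflex", manner: "liquid",    voiced: true}
  - {symbol: "r",  place: "coronal",   manner: "liquid",    voiced: true}
vowels: ["i", "I", "y", "Y", "}", "0", "e", "2", "9", "E", "u", "U", "o", "O", "A", "a", "@"]
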
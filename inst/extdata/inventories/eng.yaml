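# English (General American) phoneme inventory (SAMPA-style ASCII
# symbols). Affricates (tS, dZ), diphthongs (aI, aU, OI) and rhotic
# vowels (3`, @`) are single multi-character symbols. /j/ is
# classified as an approximant in English (unlike Swedish/Norwegian).
language: "eng"
name: "English"
markers:
  primary: "\""
  accent2: "\"\""
  secondary: "%"
  syllable: "$"
  length: ":"
consonants:
  - {symbol: "p",  place: "labial",  manner: "plosive",     voiced: false}
  - {symbol: "b",  place: "labial",  manner: "plosive",     voiced: true}
  - {symbol: "t",  place: "coronal", manner: "plosive",     voiced: false}
  - {symbol: "d",  place: "coronal", manner: "plosive",     voiced: true}
  - {symbol: "k",  place: "dorsal",  manner: "plosive",     voiced: false}
  - {symbol: "g",  place: "dorsal",  manner: "plosive",     voiced: true}
  - {symbol: "m",  place: "labial",  manner: "nasal",       voiced: true}
  - {symbol: "n",  place: "coronal", manner: "nasal",       voiced: true}
  - {symbol: "N",  place: "dorsal",  manner: "nasal",       voiced: true}
  - {symbol: "f",  place: "labial",  manner: "fricative",   voiced: false}
  - {symbol: "v",  place: "labial",  manner: "fricative",   voiced: true}
  - {symbol: "T",  place: "coronal", manner: "fricative",   voiced: false}
  - {symbol: "D",  place: "coronal", manner: "fricative",   voiced: true}
  - {symbol: "s",  place: "coronal", manner: "fricative",   voiced: false}
  - {symbol: "z",  place: "coronal", manner: "fricative",   voiced: true}
  - {symbol: "S",  place: "coronal", manner: "fricative",   voiced: false}
  - {symbol: "Z",  place: "coronal", manner: "fricative",   voiced: true}
  - {symbol: "h",  place: "glottal", manner: "fricative",   voiced: false}
  - {symbol: "tS", place: "coronal", manner: "affricate",   voiced: false}
  - {symbol: "dZ", place: "coronal", manner: "affricate",   voiced: true}
  - {symbol: "j",  place: "dorsal",  manner: "approximant", voiced: true}
  - {symbol: "w",  place: "labial",  manner: "approximant", voiced: true}
  - {symbol: "r",  place: "coronal", manner: "liquid",      voiced: true}
  - {symbol: "l",  place: "coronal", manner: "liquid",      voiced: true}
vowels: ["i", "I", "e", "E", "{", "@", "V", "U", "u", "o", "O", "A", "3`", "@`", "aI", "aU", "OI"]
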
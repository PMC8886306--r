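Package: phonsim
Title: Simulating Child Speech Error Patterns in Phonemic Transcriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating six common child speech error patterns
    (velar fronting, coronal backing, stopping, /r/-weakening, weak
    syllable deletion and cluster reduction) in SAMPA-transcribed word
    lists for Swedish, Norwegian and English, and for quantifying their
    phonological effects with five complexity and accuracy metrics: the
    Index of Phonetic Complexity (IPC), the Word Complexity Measure (WCM),
    the Percentage of Consonants Correct (PCC), the length-normalised
    Levenshtein distance (LVN) and the phonological mean length of
    utterance with its derived Proportion of Whole-word Proximity
    (pMLU/PWP). Includes token-weighted corpus aggregation from unigram
    frequency lists, Kendall tau-b rank correlation of measure-based
    severity against clinician ratings with exact permutation p-values,
    and a seeded synthetic lexicon generator with controllable
    phonotactics for end-to-end testing without corpus downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
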
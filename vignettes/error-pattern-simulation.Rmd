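---
title: "Simulating speech error patterns and measuring their phonological effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating speech error patterns and measuring their phonological effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonsim)
```

## The problem

Children acquiring a language systematically simplify adult word forms.
These simplifications — *speech error patterns*, or phonological
processes — recur across languages: velar consonants surface as
coronals (*fronting*: "key" as [ti]), fricatives as plosives
(*stopping*: "thumb" as [tʌm]), consonant clusters lose members
(*cluster reduction*: "stop" as [tap]), unstressed pre-tonic syllables
drop (*weak syllable deletion*: "banana" as [ˈnænə]). Yet the *impact*
of one and the same pattern depends on the language it is applied to:
how much damage stopping does depends on how many fricatives the
language's words contain in the first place.

`phonsim` makes that impact measurable. It applies six error patterns —
fronting, backing, stopping, /r/-weakening, weak syllable deletion and
cluster reduction — to phonemically transcribed word lists, one pattern
at a time and across the board, and quantifies the phonological effect
of each with five established measures. Backing (coronals realised as
velars) is the one *atypical* pattern of the six; the other five are
common in early typical acquisition.

## Transcriptions and inventories

Input word forms are SAMPA strings as found in pronunciation lexica:
`"` marks primary stress, `""` the Scandinavian tonal accent 2, `%`
secondary stress, `$` a syllable boundary and `:` segment length. Each
language has an editable YAML inventory classifying every consonant by
place (labial, coronal, retroflex, dorsal, glottal), manner (plosive,
fricative, affricate, nasal, liquid, approximant, tap) and voicing.
Multi-character symbols — English affricates `tS`/`dZ`, diphthongs,
retroflexes written `t'`, `s'`, … — are tokenized greedily, longest
first, so tokenization is deterministic.

```{r}
t <- parse_transcription('""sp2:$ket', "swe")   # Swedish "spöket"
t
consonant_tokens(t)$symbol
```

Two conventions matter downstream. First, a long vowel such as `2:` is
*one segment* (for pMLU) but *two characters* (for the normalised
Levenshtein distance, which runs on the raw string, markers and
delimiters included — `""sp2:$ket` has 10 characters). Second, prosody
markers belong to the syllable, not to any segment.

A note on classification choices that the measures are sensitive to:
/j/ is classified as a voiced palatal *fricative* in Swedish and
Norwegian but as an *approximant* in English, and the rhotic is a
voiced alveolar liquid (a tap in Norwegian). Because /r/-weakening
rewrites /r/ → /j/, this single classification decision makes the same
substitution *raise* word complexity in the Scandinavian languages and
*lower* it in English (see below).

## The six patterns

Each simulator takes a transcription and returns the "misarticulated"
form plus an *edit record* — the per-segment substitutions and
deletions it performed. The edit record is the simulation's ground
truth: accuracy measures are derived from it, not from re-aligning the
two strings.

* **fronting** `k→t, g→d, ŋ→n`; **backing** is its reverse (with
  retroflexes folded in for Swedish/Norwegian).
* **stopping** maps fricatives/affricates to plosives (`f→p, v→b, s→t,
  …`). A mapped fricative standing directly before a plosive in the
  same cluster is *deleted* instead, so /²spøː.ket/ loses its /s/
  rather than gaining an illegal plosive–plosive onset.
* **/r/-weakening** rewrites every rhotic as /j/ (the cross-linguistic
  common denominator, even though [w] is the commoner English
  realisation).
* **weak syllable deletion** finds the first syllable bearing primary
  stress or a tonal accent and, when it is not word-initial, deletes
  the single syllable immediately before it — one syllable only, so
  a long pre-tonic stretch keeps everything except the last pre-tonic
  syllable.
* **cluster reduction** reduces every *syllable onset* of two or more
  consonants (codas are untouched, and a coda–onset sequence across a
  syllable boundary is not a cluster). The retention table is
  per-language: three-member onsets keep the second member, /s/-initial
  two-member onsets keep the second, all other two-member onsets keep
  the first — with the language-specific exception that English /sl/
  keeps the /s/ ("slide" → [saɪd]) while Swedish /sl/ keeps the /l/
  ("slåss" → [lɔs]).

Patterns are never composed; each is applied alone to the original
form. All six are idempotent, applied across the board (every
applicable token), and can only shrink a word, never grow it.

```{r}
rules <- pattern_rules("swe")
apply_stopping(t, rules)$t$raw
apply_stopping(t, rules)$edits
```

## The five measures

Two *structural* measures score a single form in isolation; their
error-minus-original difference quantifies the complexity change
(negative = simplification):

* **IPC** (Index of Phonetic Complexity), default table: +1 per
  singleton (non-cluster) fricative or affricate, +1 per dorsal
  consonant, +1 per onset/coda cluster, +1 more if the cluster is
  heterorganic (members spanning two or more places). The rhotic and
  /j/ are excluded outright — they earn no points *and* contribute no
  place when judging heterorganicity. That exclusion is what makes
  /r/-weakening exactly IPC-neutral: /tr/ → /tj/ neither gains nor
  loses a place contrast when both excluded members are invisible.
  This compact table reproduces every published single-word IPC value
  this package tests against; the full original parameter set can be
  supplied as an alternative YAML config.
* **WCM** (Word Complexity Measure), the original parameter set: ≥3
  syllables; primary stress/accent on a non-initial syllable (no point
  for an initial tonal accent of either kind); word-final consonant;
  each cluster; each velar; each liquid; each fricative/affricate, with
  one extra point when voiced. Under the Swedish /j/-as-fricative
  classification, /r/ (liquid, 1) → /j/ (voiced fricative, 2) is a +1
  per token; in English /j/ is an unscored approximant, so the same
  substitution is a −1.

Two *relational* measures compare the two forms:

* **PCC** (Percentage of Consonants Correct): the share of the
  original's consonants the simulation left untouched, read off the
  edit record. Words with no consonants are undefined and excluded
  from aggregation (they are counted in the diagnostics).
* **LVN**: the Levenshtein distance between the two raw SAMPA strings
  divided by the sum of their lengths, a symmetric dissimilarity in
  [0, 1).

And one *combined* measure:

* **pMLU/PWP**: a form's pMLU is its segment count plus its number of
  correct consonants; the PWP divides the production's pMLU by the
  target's. The textbook contrast: /nana/ scores 6/9 ≈ .67 against
  "banana" but 6/6 = 1.0 against "nanny" — same production, very
  different proximity to target.

```{r}
score_word("spöket", '""sp2:$ket', "stopping", language = "swe")[
  , c("sampa_err", "ipc_diff", "wcm_diff", "pcc", "lvn", "pwp")]
```

One published decomposition is knowingly not chased: the illustrative
single-word WCM absolutes (2 and 0) for this example omit the velar
and final-consonant points that the full parameter set assigns (our
absolutes are 4 and 2). The *difference* −2 — the quantity every
analysis uses — is identical either way, and only a full table makes
backing come out as the complexity-increasing pattern it must be.

## Corpus aggregation

`aggregate_effects()` scores each word *type* once and weights it by
its token count, which is exactly equivalent to expanding the corpus
token by token. Conventions:

* hapax legomena (count 1) are excluded up front (`exclude_hapax()`);
* the structural and combined measures (IPC, WCM, PWP) aggregate over
  open-class tokens only — closed-class (function-word) lists are an
  input, with `top_frequent()` emitting the 100 most frequent types as
  candidates for manual curation; PCC and LVN aggregate over *all*
  tokens;
* one transcription per word: the first lexicon entry wins; words
  without an entry are skipped and counted (the corpus studies this
  mirrors fell back on grapheme-to-phoneme conversion, which is out of
  scope here);
* SD is the population SD over tokens, SEM = SD/√n_tokens;
* words where the pattern does not apply stay in (effect 0, PCC 100)
  — that is what pushes corpus PCC means toward the ceiling; an
  `applicable_only` switch provides the sensitivity analysis.

## Rank analysis against clinician intuition

Given a six-row table of per-pattern mean effects plus mean clinician
severity rankings (1 = least, 6 = most severe), the face-validity
question is whether any measure orders the patterns the way clinicians
do. `severity_correlation_matrix()` computes pairwise Kendall τ-b —
average-rank tie correction, (C−D)/√((n₀−n₁)(n₀−n₂)) — taking the
structural measures as absolute values (a complexity change of either
sign is an effect).

With n = 6 patterns the normal approximation for p is unreliable, so
p-values are exact by default: full enumeration of all 6! = 720
orderings. Published analyses of this design typically report the
tie-corrected asymptotic p (our `exact_max_n = 0`), which is uniformly
smaller at this n; the τ values are identical either way. On the
bundled reference table the two relational measures agree nearly
perfectly with each other (τ = −.87) and the combined PWP tracks both
structural measures (τ = −.83), but *no* measure correlates
significantly with clinical intuition — the largest association is
PWP's τ = −.55 — corroborating that phonological effect size is not a
proxy for intelligibility impact.

```{r}
m <- severity_correlation_matrix(ref_rank_table())
round(m$tau, 2)
```

## Synthetic lexica

`generate_lexicon()` builds seeded, inventory-valid word lists with
controllable phonotactics: dials for the rates of onset clusters,
fricatives, velars, rhotics and pre-tonic (second-syllable) stress,
syllable counts within the language's C₀₋₃VC₀₋₁ templates used here,
and Zipf-like token counts floored at 2 (hapax rows appear only by
explicit injection, so hapax filtering is tested deliberately). Each
dial has a matched pattern whose effect it feeds — more fricatives,
bigger stopping effect — giving monotone dose-response properties that
the test suite checks over multiple seeds. Default dial values (0.2
clusters, 0.25 fricatives, 0.15 velars, 0.1 rhotics, 0.25 pre-tonic)
sit in the range typical of Germanic child-directed vocabulary, and the
test problem sizes (15–40 types, a few hundred tokens) keep the whole
suite fast while still exercising every aggregation pathway.

What the generator does *not* emulate: real lexical statistics
(neighbourhood structure, phonotactic probability, morphology),
inconsistent or context-conditioned misarticulation, and transcription
noise. Passing tests therefore validate the *machinery* — parsing,
rules, metrics, weighting — on realistic shapes, not any empirical
claim about a particular language's corpus.

## Numerical and edge-case decisions

* Vowel-less words ("hm") are rejected by default (`lenient = TRUE`
  parses them as onset-only syllables); consonants *between* two
  vowels inside one syllable are a syllabification error and rejected.
* Syllable boundaries and stress come from the lexicon verbatim; no
  automatic syllabification.
* Onsets longer than three consonants have no retention rule: left
  unchanged and counted in `n_unmatched_clusters`.
* A word's PCC with zero consonants is `NA`, never 0 or 100.
* Determinism throughout: rule application has no randomness; the
  generator is a pure function of its seed.

## Limitations

The simulation is across-the-board and context-free by design; real
children apply patterns variably and context-sensitively. PCC here is
simulation-derived — with only a target and an observed transcription
(no edit record), PCC computation would need alignment, which this
package does not do. The bundled configurations cover Swedish,
Norwegian and English; other languages need an inventory, a pattern
file and a scoring file, all plain YAML.
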
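# phonsim

Simulation of child speech error patterns in phonemically transcribed
word lists, with quantification of their phonological effects.

## What it is for

Children acquiring a language simplify adult word forms in systematic
ways: velars surface as coronals (*fronting*, "key" → [ti]),
fricatives as plosives (*stopping*, "thumb" → [tʌm]), onset clusters
lose members (*cluster reduction*, "stop" → [tap]), pre-tonic
syllables drop (*weak syllable deletion*, "banana" → [ˈnænə]). How
much such a pattern distorts speech depends on the language: stopping
can only do damage in proportion to how many fricatives the language's
words contain.

`phonsim` is for researchers and clinicians who want to measure that.
It applies six error patterns — fronting, backing (the one atypical
pattern), stopping, /r/-weakening, weak syllable deletion, cluster
reduction — to SAMPA-transcribed lexica for Swedish, Norwegian and
English, one pattern at a time and across the board, and quantifies
each pattern's effect with five measures:

| measure | type | definition |
|---|---|---|
| IPC | structural | additive phonetic-complexity points (fricatives, dorsals, clusters, heterorganic clusters) |
| WCM | structural | additive word-complexity points (word patterns, syllable structures, sound classes) |
| PCC | relational | % of the target's consonants left untouched |
| LVN | relational | Levenshtein distance / summed string lengths |
| pMLU → PWP | combined | (segments + correct consonants); PWP = pMLU(production)/pMLU(target) |

Structural effects are reported as error-minus-original differences
(negative = simplification). A token-weighted corpus pipeline
aggregates per-pattern effects over unigram frequency lists (hapax
excluded; structural measures on open-class words, relational on all
tokens), and a Kendall τ-b rank analysis (exact permutation p at
small n) relates measure-based severity orderings to clinicians'
intuitive severity rankings.

## Worked example

The Swedish word *spöket* "the ghost", SAMPA `""sp2:$ket` (accent 2,
two syllables), under stopping — the cluster-internal /s/ is deleted:

```r
library(phonsim)
score_word("spöket", '""sp2:$ket', "stopping", language = "swe")
#>     word  pattern sampa_orig sampa_err ipc_orig ipc_err ipc_diff wcm_orig
#> 1 spöket stopping ""sp2:$ket ""p2:$ket        3       1       -2        4
#>   wcm_err wcm_diff pcc        lvn pmlu_orig pmlu_err pwp n_edits
#> 1       2       -2  75 0.05263158        10        8 0.8       1
```

Reading the row: losing the /s/ removes the cluster, its heterorganic
bonus and the fricative, so both complexity scores drop by 2; three of
four consonants survive (PCC 75%); one edit over 10 + 9 characters
gives LVN 1/19 ≈ 0.053; pMLU falls from 10 (6 segments + 4 consonants)
to 8, so the production retains 80% whole-word proximity (PWP 0.8).

The face-validity analysis, run on the bundled six-pattern effect
summary for Swedish child speech:

```r
m <- severity_correlation_matrix(ref_rank_table())
round(m$tau["clinical", ], 2)
#> clinical      wcm      ipc      pcc      lvn      pwp
#>     1.00     0.33     0.33    -0.20     0.33    -0.55
```

No measure tracks clinical intuition about intelligibility impact —
the motivating negative result — while the measures correlate strongly
with each other (e.g. LVN–PCC τ = −.87, PWP–WCM τ = −.83).

Synthetic corpora with controllable phonotactics support end-to-end
experiments without corpus downloads:

```r
fx <- generate_lexicon(fixture_spec("swe", n_types = 40, seed = 1,
                                    p_fricative = 0.4))
aggregate_effects("stopping", exclude_hapax(fx$freq), fx$lexicon, "swe")
```

A thin CLI over the same functions lives in `inst/scripts/phonsim`
(subcommands `simulate`, `score`, `aggregate`, `correlate`,
`fixtures`).

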
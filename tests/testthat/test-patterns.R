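rules_cache <- lapply(
  stats::setNames(nm = available_languages()), pattern_rules)

test_that("published example words transform to the reported child forms", {
  ex <- pattern_examples()
  for (i in seq_len(nrow(ex))) {
    r <- rules_cache[[ex$lang[i]]]
    t <- parse_transcription(ex$input[i], r$inventory)
    out <- apply_pattern(t, ex$pattern[i], r)
    expect_identical(out$t$raw, ex$expected[i],
                     label = sprintf("%s/%s '%s'", ex$lang[i], ex$pattern[i],
                                     ex$word[i]))
  }
  expect_gte(nrow(ex), 20L)
})

test_that("words with no applicable context come back untouched", {
  cases <- list(
    c("swe", "\"ba$na", "fronting"),     # no velars
    c("swe", "\"ba$la", "backing"),      # no coronal stops/nasals
    c("eng", "\"mun", "stopping"),       # no fricatives
    c("swe", "\"ba$la", "r_weakening"),  # r-free
    c("eng", "\"n{$n@", "weak_syllable_deletion"),  # initial stress
    c("eng", "\"tAp", "cluster_reduction")          # no onset cluster
  )
  for (cs in cases) {
    t <- parse_transcription(cs[2], rules_cache[[cs[1]]]$inventory)
    out <- apply_pattern(t, cs[3], rules_cache[[cs[1]]])
    expect_identical(out$t$raw, t$raw)
    expect_equal(nrow(out$edits), 0L)
  }
})

test_that("stopping deletes a fricative before a plosive, substitutes elsewhere", {
  r <- rules_cache$swe
  out <- apply_stopping(parse_transcription("\"\"sp2:$ket", "swe"), r)
  expect_identical(out$t$raw, "\"\"p2:$ket")
  expect_equal(out$edits$kind, "delete")
  expect_equal(out$edits$symbol, "s")
  # coda fricative+plosive: same deletion rule
  out2 <- apply_stopping(parse_transcription("\"vEst", "swe"), r)
  expect_identical(out2$t$raw, "\"bEt")
  expect_equal(out2$edits$kind, c("substitute", "delete"))
  # substitute_anyway disables the deletion
  r2 <- r
  r2$stopping$before_plosive <- "substitute_anyway"
  out3 <- apply_stopping(parse_transcription("\"\"sp2:$ket", "swe"), r2)
  expect_identical(out3$t$raw, "\"\"tp2:$ket")
})

test_that("weak syllable deletion removes exactly the pre-tonic syllable", {
  r <- rules_cache$eng
  out <- apply_weak_syllable_deletion(parse_transcription("b@$\"n{$n@", "eng"), r)
  expect_identical(out$t$raw, "\"n{$n@")
  expect_setequal(out$edits$kind, "delete")
  expect_equal(sum(out$edits$is_consonant), 1L)  # the /b/
  # only ONE pre-tonic syllable goes, not all
  out2 <- apply_weak_syllable_deletion(
    parse_transcription("le:$v@$pas$\"tEj", "swe"), rules_cache$swe)
  expect_identical(out2$t$raw, "le:$v@$\"tEj")
  # accent-2 marked syllables anchor too
  out3 <- apply_weak_syllable_deletion(
    parse_transcription("pa$\"\"tA:$ta", "swe"), rules_cache$swe)
  expect_identical(out3$t$raw, "\"\"tA:$ta")
})

test_that("cluster reduction is onset-only and language-specific", {
  # codas untouched
  out <- apply_cluster_reduction(parse_transcription("\"vans", "swe"),
                                 rules_cache$swe)
  expect_identical(out$t$raw, "\"vans")
  # medial onset clusters are reduced; a coda+onset split is not a cluster
  out2 <- apply_cluster_reduction(parse_transcription("\"plOs$ter", "swe"),
                                  rules_cache$swe)
  expect_identical(out2$t$raw, "\"pOs$ter")
  # same cluster, different language, different survivor
  sl_en <- apply_cluster_reduction(parse_transcription("\"slaId", "eng"),
                                   rules_cache$eng)
  sl_sw <- apply_cluster_reduction(parse_transcription("\"slOs", "swe"),
                                   rules_cache$swe)
  expect_identical(sl_en$t$raw, "\"saId")
  expect_identical(sl_sw$t$raw, "\"lOs")
  expect_equal(attr(out$edits, "unmatched"), 0L)
})

test_that("every pattern is idempotent and never grows the word", {
  set.seed(303)
  for (lang in available_languages()) {
    r <- rules_cache[[lang]]
    fx <- generate_lexicon(fixture_spec(lang, n_types = 25, seed = 7,
                                        p_onset_cluster = 0.4,
                                        p_fricative = 0.3, p_velar = 0.2,
                                        p_rhotic = 0.1, p_pretonic = 0.4))
    for (raw in fx$lexicon) {
      t <- parse_transcription(raw, r$inventory)
      for (pat in pattern_names()) {
        out <- apply_pattern(t, pat, r)
        expect_equal(n_segments(out$t),
                     n_segments(t) - sum(out$edits$kind == "delete"))
        again <- apply_pattern(out$t, pat, r)
        expect_identical(again$t$raw, out$t$raw,
                         label = paste(lang, pat, raw))
        # every edit references a resolvable original consonant
        idx <- out$edits$index[out$edits$is_consonant]
        expect_true(all(idx >= 1 & idx <= nrow(consonant_tokens(t))))
        expect_false(anyDuplicated(idx) > 0)
      }
    }
  }
})

test_that("apply_pattern dispatches and rejects unknown names", {
  t <- parse_transcription("\"\"kA:$ka", "swe")
  expect_identical(apply_pattern(t, "fronting", rules_cache$swe)$t$raw,
                   apply_fronting(t, rules_cache$swe)$t$raw)
  expect_error(apply_pattern(t, "gliding", rules_cache$swe), "unknown pattern")
  expect_error(apply_fronting(t, rules_cache$eng), "does not match")
})
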
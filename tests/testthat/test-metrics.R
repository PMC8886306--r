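swe_scoring <- load_scoring("swe")

test_that("IPC reproduces the published Swedish absolutes", {
  expect_equal(ipc_score(parse_transcription("\"\"g0$bar", "swe")), 1)
  expect_equal(ipc_score(parse_transcription("\"\"d0$bar", "swe")), 0)
  expect_equal(ipc_score(parse_transcription("\"\"sp2:$ket", "swe")), 3)
  expect_equal(ipc_score(parse_transcription("\"\"p2:$ket", "swe")), 1)
  expect_equal(ipc_score(parse_transcription("a", "swe")), 0)
})

test_that("r-weakening leaves IPC exactly unchanged, including cluster place", {
  r <- pattern_rules("swe")
  # /tr/ is homorganic only because the excluded rhotic contributes no place;
  # substituting /j/ must not flip heterorganicity
  for (raw in c("\"tru:$la", "\"bru:$na", "\"ka$rat", "\"d9r")) {
    t <- parse_transcription(raw, "swe")
    out <- apply_r_weakening(t, r)
    expect_equal(structural_diff(t, out$t, swe_scoring)[["ipc"]], 0,
                 label = raw)
  }
})

test_that("WCM reflects the language-dependent classification of /j/", {
  # Swedish: liquid /r/ (1 point) -> voiced fricative /j/ (2 points)
  t <- parse_transcription("\"\"ram$la", "swe")
  out <- apply_r_weakening(t, pattern_rules("swe"))
  expect_equal(structural_diff(t, out$t, swe_scoring)[["wcm"]], +1)
  # English: liquid /r/ (1 point) -> approximant /j/ (0 points)
  te <- parse_transcription("\"rEd", "eng")
  oute <- apply_r_weakening(te, pattern_rules("eng"))
  expect_equal(structural_diff(te, oute$t, load_scoring("eng"))[["wcm"]], -1)
  # backing adds velar points
  tb <- parse_transcription("\"tu", "eng")
  outb <- apply_backing(tb, pattern_rules("eng"))
  expect_equal(structural_diff(tb, outb$t, load_scoring("eng"))[["wcm"]], +1)
})

test_that("PCC follows the edit record", {
  t <- parse_transcription("\"\"sp2:$ket", "swe")
  out <- apply_stopping(t, pattern_rules("swe"))
  expect_equal(pcc(t, out$edits), 75)
  expect_equal(pcc(t, out$edits[0, ]), 100)
  all_subst <- apply_backing(parse_transcription("\"ta$ta", "swe"),
                             pattern_rules("swe"))
  expect_equal(pcc(parse_transcription("\"ta$ta", "swe"), all_subst$edits), 0)
  # zero-consonant words are undefined, not zero
  expect_true(is.na(pcc(parse_transcription("a", "swe"), out$edits[0, ])))
  bad <- out$edits; bad$index <- 9L
  expect_error(pcc(t, bad), "does not exist")
})

test_that("levenshtein matches a DP oracle and lvn is a bounded symmetric ratio", {
  expect_equal(levenshtein("\"\"sp2:$ket", "\"\"p2:$ket"), 1)
  expect_equal(lvn("\"\"sp2:$ket", "\"\"p2:$ket"), 1 / 19)
  set.seed(404)
  alpha <- c(letters[1:6], ":", "$", "\"")
  rand_str <- function() paste(sample(alpha, sample(0:8, 1), TRUE), collapse = "")
  for (i in 1:500) {
    a <- rand_str(); b <- rand_str()
    expect_equal(levenshtein(a, b), dp_levenshtein(a, b))
    if (nchar(a) + nchar(b) > 0) {
      expect_equal(lvn(a, b), lvn(b, a))
      expect_gte(lvn(a, b), 0)
      # strictly below 1 whenever both strings are non-empty
      if (nchar(a) > 0 && nchar(b) > 0) expect_lt(lvn(a, b), 1)
    }
  }
  # triangle inequality, spot-checked
  for (i in 1:100) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
  expect_error(lvn("", ""), "undefined")
})

test_that("pMLU and PWP reproduce the published word examples", {
  spoket <- parse_transcription("\"\"sp2:$ket", "swe")
  expect_equal(pmlu(spoket), 10)  # 6 segments + 4 consonants
  stopped <- apply_stopping(spoket, pattern_rules("swe"))
  expect_equal(pmlu(stopped$t, 3), 8)
  expect_equal(pwp(spoket, stopped$t, stopped$edits), 0.8)
  # /nana/ for "banana" vs for "nanny"
  nana <- parse_transcription("\"nA$nA", "eng")
  banana <- parse_transcription("b@$\"n{$n@", "eng")
  nanny <- parse_transcription("\"n{$ni", "eng")
  expect_equal(pmlu(nana, 2) / pmlu(banana), 6 / 9)
  expect_equal(pmlu(nana, 2) / pmlu(nanny), 1)
  expect_equal(pmlu(parse_transcription("a", "swe")), 1)
  expect_error(pmlu(nana, 7), "exceeds")
})

test_that("score_word ties the five metrics together consistently", {
  row <- score_word("spöket", "\"\"sp2:$ket", "stopping", language = "swe")
  expect_equal(row$ipc_diff, -2)
  expect_equal(row$wcm_diff, -2)
  expect_equal(row$pcc, 75)
  expect_equal(row$lvn, 1 / 19, tolerance = 1e-12)
  expect_equal(row$pwp, 0.8)
  expect_error(score_word("x", "\"ta", "gliding", language = "swe"),
               "unknown pattern")
})

test_that("neutral words pin all five metrics to their no-effect values", {
  set.seed(505)
  fx <- generate_lexicon(fixture_spec("swe", n_types = 20, seed = 5))
  r <- pattern_rules("swe")
  for (w in names(fx$lexicon)) {
    for (pat in pattern_names()) {
      row <- score_word(w, fx$lexicon[[w]], pat, "swe", rules = r)
      untouched <- row$n_edits == 0
      expect_equal(row$pcc == 100, untouched)
      expect_equal(row$lvn == 0, untouched)
      expect_equal(row$pwp == 1, untouched)
      if (untouched) {
        expect_equal(row$ipc_diff, 0)
        expect_equal(row$wcm_diff, 0)
      }
      # deletions/substitutions only: proximity can never exceed the target
      expect_lte(row$pwp, 1)
      expect_lte(row$pmlu_err, row$pmlu_orig)
      # delete-only edit records move LVN by exactly the deleted characters
      ed <- apply_pattern(parse_transcription(fx$lexicon[[w]], "swe"), pat, r)
      if (nrow(ed$edits) > 0 && all(ed$edits$kind == "delete")) {
        expect_equal(levenshtein(row$sampa_orig, row$sampa_err),
                     nchar(row$sampa_orig) - nchar(row$sampa_err))
      }
    }
  }
})
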
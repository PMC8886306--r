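#' Percentage of Consonants Correct (PCC)
#'
#' The proportion of consonants in the original transcription that the
#' simulation left untouched, as a percentage. Because the simulation's
#' edit record is the ground truth, the PCC is derived directly from it
#' rather than from re-alignment of the two strings.
#'
#' @param orig The original `phonsim_transcription`.
#' @param edits The edit record produced from `orig` by a pattern
#'   simulator.
#' @return Percentage in \[0, 100\], or `NA` for a word without
#'   consonants (such words are excluded from aggregation).
#' @export
pcc <- function(orig, edits) {
  ncons <- nrow(consonant_tokens(orig))
  affected <- edits$index[edits$is_consonant]
  if (length(affected)) {
    if (anyNA(affected) || any(affected < 1L | affected > ncons))
      stop("edit record references a consonant that does not exist in the original")
    if (anyDuplicated(affected))
      stop("edit record touches the same consonant twice")
  }
  if (ncons == 0L) return(NA_real_)
  100 * (ncons - length(affected)) / ncons
}

#' Levenshtein distance between two strings
#'
#' Minimal number of single-character insertions, deletions or
#' substitutions turning `a` into `b`, computed on the raw SAMPA
#' character sequences (prosodic markers and syllable delimiters
#' included).
#'
#' @param a,b Strings.
#' @return Non-negative integer.
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b)[1, 1])
}

#' Length-normalised Levenshtein distance (LVN)
#'
#' [levenshtein()] divided by the summed character lengths of the two
#' strings; a symmetric dissimilarity in \[0, 1).
#'
#' @param a,b Strings; not both empty.
#' @return Ratio in \[0, 1).
#' @examples
#' lvn("\"\"sp2:$ket", "\"\"p2:$ket")  # 1/19
#' @export
lvn <- function(a, b) {
  n <- nchar(a) + nchar(b)
  if (n == 0L) stop("lvn is undefined for two empty strings")
  levenshtein(a, b) / n
}

#' Phonological mean length of utterance (pMLU) of a word form
#'
#' The number of segments in the form plus the number of correct
#' consonants. For a target (adult) form every consonant is correct,
#' so its pMLU is segment count plus consonant count; for a simulated
#' production the correct-consonant count is the number of original
#' consonants left unaffected.
#'
#' @param t A `phonsim_transcription`.
#' @param correct_consonants Number of correct consonants; defaults to
#'   the form's own consonant count (i.e. a target form).
#' @return pMLU points.
#' @examples
#' pmlu(parse_transcription("\"\"sp2:$ket", "swe"))  # 6 segments + 4 consonants
#' @export
pmlu <- function(t, correct_consonants = nrow(consonant_tokens(t))) {
  if (correct_consonants < 0) stop("'correct_consonants' must be >= 0")
  if (correct_consonants > nrow(consonant_tokens(t)))
    stop("'correct_consonants' exceeds the form's consonant count")
  n_segments(t) + correct_consonants
}

#' Proportion of Whole-word Proximity (PWP)
#'
#' pMLU of the simulated production divided by pMLU of the target.
#' For the six patterns (substitutions and deletions only) the PWP lies
#' in (0, 1\]; 1 means the word was untouched.
#'
#' @param orig Target `phonsim_transcription`.
#' @param err Simulated production.
#' @param edits Edit record that produced `err` from `orig`.
#' @return Ratio in (0, 1\] for deletion/substitution-only edits.
#' @export
pwp <- function(orig, err, edits) {
  ncons <- nrow(consonant_tokens(orig))
  unaffected <- ncons - sum(edits$is_consonant)
  denom <- pmlu(orig)
  if (denom == 0) stop("target pMLU is zero")
  pmlu(err, unaffected) / denom
}

#' Score one word under one error pattern
#'
#' Applies the pattern and fills all five metrics consistently: the
#' single edit record feeds the PCC and the PWP, and the LVN is
#' computed on the two raw SAMPA strings.
#'
#' @param word Orthographic word (carried through to the output).
#' @param t Target transcription (a `phonsim_transcription`, or a raw
#'   SAMPA string parsed against `language`).
#' @param pattern One of [pattern_names()].
#' @param language Language code; defaults to the transcription's.
#' @param scoring A [load_scoring()] configuration.
#' @param rules A [pattern_rules()] object.
#' @return One-row data frame with columns `word`, `pattern`,
#'   `sampa_orig`, `sampa_err`, `ipc_orig`, `ipc_err`, `ipc_diff`,
#'   `wcm_orig`, `wcm_err`, `wcm_diff`, `pcc`, `lvn`, `pmlu_orig`,
#'   `pmlu_err`, `pwp`, `n_edits`.
#' @examples
#' score_word("spöket", "\"\"sp2:$ket", "stopping", language = "swe")
#' @export
score_word <- function(word, t, pattern, language = NULL,
                       scoring = NULL, rules = NULL) {
  if (is.character(t)) {
    if (is.null(language)) stop("'language' is required when 't' is a raw string")
    t <- parse_transcription(t, language)
  }
  if (is.null(language)) language <- t$language
  if (is.null(scoring)) scoring <- load_scoring(language)
  if (is.null(rules)) rules <- pattern_rules(language)
  res <- apply_pattern(t, pattern, rules)
  err <- res$t
  edits <- res$edits
  ipc_o <- ipc_score(t, scoring); ipc_e <- ipc_score(err, scoring)
  wcm_o <- wcm_score(t, scoring); wcm_e <- wcm_score(err, scoring)
  ncons <- nrow(consonant_tokens(t))
  data.frame(
    word = word, pattern = pattern,
    sampa_orig = t$raw, sampa_err = err$raw,
    ipc_orig = ipc_o, ipc_err = ipc_e, ipc_diff = ipc_e - ipc_o,
    wcm_orig = wcm_o, wcm_err = wcm_e, wcm_diff = wcm_e - wcm_o,
    pcc = pcc(t, edits),
    lvn = lvn(t$raw, err$raw),
    pmlu_orig = pmlu(t),
    pmlu_err = pmlu(err, ncons - sum(edits$is_consonant)),
    pwp = pwp(t, err, edits),
    n_edits = nrow(edits),
    stringsAsFactors = FALSE
  )
}
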
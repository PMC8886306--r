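#' The six simulated error patterns
#'
#' @return Character vector of pattern names accepted by
#'   [apply_pattern()].
#' @export
pattern_names <- function() {
  c("fronting", "backing", "stopping", "r_weakening",
    "weak_syllable_deletion", "cluster_reduction")
}

#' Load pattern rule tables for a language
#'
#' Rules are editable YAML: substitution maps for the segmental patterns
#' (fronting, backing, stopping, r-weakening), the anchor convention for
#' weak syllable deletion, and the cluster-retention table for cluster
#' reduction. All symbols are validated against the inventory.
#'
#' @param language Bundled language code or path to a pattern YAML file.
#' @param inventory Inventory to validate against; defaults to the
#'   language's bundled inventory.
#' @return Object of class `phonsim_rules`.
#' @export
pattern_rules <- function(language, inventory = NULL) {
  cfg <- yaml::read_yaml(resolve_config_path(language, "patterns"))
  if (is.null(inventory)) inventory <- load_inventory(cfg$language)
  syms <- c(inventory$consonants$symbol, inventory$vowels)
  for (pat in c("fronting", "backing", "stopping")) {
    m <- cfg[[pat]]$map
    bad <- setdiff(c(names(m), unlist(m)), syms)
    if (length(bad))
      stop("pattern '", pat, "' references symbols missing from the ",
           cfg$language, " inventory: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(c(cfg$r_weakening$rhotics, cfg$r_weakening$target,
                   cfg$cluster_reduction$s_onsets), syms)
  if (length(bad))
    stop("pattern rules reference unknown symbols: ", paste(bad, collapse = ", "))
  rules <- c(cfg, list(inventory = inventory))
  class(rules) <- "phonsim_rules"
  rules
}

#' @export
print.phonsim_rules <- function(x, ...) {
  cat(sprintf("<phonsim_rules> %s: %s\n", x$language,
              paste(pattern_names(), collapse = ", ")))
  invisible(x)
}

empty_edits <- function() {
  data.frame(kind = character(0), index = integer(0),
             symbol = character(0), replacement = character(0),
             is_consonant = logical(0), stringsAsFactors = FALSE)
}

edit_row <- function(kind, index, symbol, replacement, is_consonant) {
  data.frame(kind = kind, index = index, symbol = symbol,
             replacement = replacement, is_consonant = is_consonant,
             stringsAsFactors = FALSE)
}

# consonant ordinal (1..n over the word's consonants) per segment row
consonant_ordinal <- function(segments) {
  ord <- cumsum(segments$is_consonant)
  ord[!segments$is_consonant] <- NA_integer_
  ord
}

check_language <- function(t, rules) {
  if (!identical(t$language, rules$language))
    stop("transcription language '", t$language,
         "' does not match rule language '", rules$language, "'")
}

# shared engine for pure substitution patterns (fronting, backing,
# r-weakening): every matching consonant replaced, features refreshed
apply_substitution_map <- function(t, map, inventory) {
  segs <- t$segments
  ord <- consonant_ordinal(segs)
  hit <- which(segs$is_consonant & segs$symbol %in% names(map))
  if (length(hit) == 0L) return(list(t = t, edits = empty_edits()))
  new_sym <- unlist(map[segs$symbol[hit]], use.names = FALSE)
  edits <- edit_row("substitute", ord[hit], segs$symbol[hit], new_sym, TRUE)
  feats <- segment_features(new_sym, inventory)
  segs$symbol[hit] <- new_sym
  segs$place[hit] <- feats$place
  segs$manner[hit] <- feats$manner
  segs$voiced[hit] <- feats$voiced
  t$segments <- segs
  list(t = rebuild_transcription(t), edits = edits)
}

#' Simulate velar fronting
#'
#' Replaces every velar plosive/nasal with its coronal counterpart
#' (k -> t, g -> d, ng -> n), across the whole word.
#'
#' @param t A `phonsim_transcription`.
#' @param rules A [pattern_rules()] object for the same language.
#' @return List with elements `t` (the "misarticulated" transcription)
#'   and `edits` (the edit record: one row per substituted or deleted
#'   segment, with the consonant ordinal in the original word).
#' @examples
#' r <- pattern_rules("swe")
#' apply_fronting(parse_transcription("\"\"kA:$ka", "swe"), r)$t$raw
#' @export
apply_fronting <- function(t, rules) {
  check_language(t, rules)
  apply_substitution_map(t, rules$fronting$map, rules$inventory)
}

#' Simulate coronal backing
#'
#' Replaces coronal (and, for Swedish/Norwegian, retroflex) plosives and
#' nasals with velars (t -> k, d -> g, n -> ng). The reverse of
#' fronting, and the one atypical pattern of the six.
#'
#' @inheritParams apply_fronting
#' @return As [apply_fronting()].
#' @export
apply_backing <- function(t, rules) {
  check_language(t, rules)
  apply_substitution_map(t, rules$backing$map, rules$inventory)
}

#' Simulate stopping of fricatives and affricates
#'
#' Singleton fricatives/affricates are substituted by plosives per the
#' language's map (f -> p, v -> b, s -> t, ...). A mapped fricative
#' standing immediately before a plosive inside the same onset or coda
#' cluster is deleted instead (so /sp/ loses the /s/ rather than
#' becoming an illegal plosive-plosive onset); set
#' `before_plosive: "substitute_anyway"` in the rule file to disable.
#'
#' @inheritParams apply_fronting
#' @return As [apply_fronting()].
#' @examples
#' r <- pattern_rules("swe")
#' apply_stopping(parse_transcription("\"\"sp2:$ket", "swe"), r)$t$raw
#' @export
apply_stopping <- function(t, rules) {
  check_language(t, rules)
  map <- rules$stopping$map
  delete_before_plosive <- !identical(rules$stopping$before_plosive,
                                      "substitute_anyway")
  segs <- t$segments
  ord <- consonant_ordinal(segs)
  hit <- which(segs$is_consonant & segs$symbol %in% names(map))
  if (length(hit) == 0L) return(list(t = t, edits = empty_edits()))
  nseg <- nrow(segs)
  del <- logical(nseg)
  edits <- empty_edits()
  for (i in hit) {
    next_in_cluster <- i < nseg &&
      segs$syllable[i + 1L] == segs$syllable[i] &&
      segs$role[i + 1L] == segs$role[i] &&
      segs$role[i] %in% c("onset", "coda") &&
      segs$is_consonant[i + 1L]
    if (delete_before_plosive && next_in_cluster &&
        segs$manner[i + 1L] == "plosive") {
      del[i] <- TRUE
      edits <- rbind(edits, edit_row("delete", ord[i], segs$symbol[i],
                                     NA_character_, TRUE))
    } else {
      new_sym <- map[[segs$symbol[i]]]
      edits <- rbind(edits, edit_row("substitute", ord[i], segs$symbol[i],
                                     new_sym, TRUE))
      feats <- segment_features(new_sym, rules$inventory)
      segs$symbol[i] <- new_sym
      segs$place[i] <- feats$place
      segs$manner[i] <- feats$manner
      segs$voiced[i] <- feats$voiced
    }
  }
  t$segments <- segs[!del, ]
  list(t = rebuild_transcription(t), edits = edits)
}

#' Simulate /r/-weakening
#'
#' Every rhotic (the language's rhotic set: /r/, plus the retroflex flap
#' in Norwegian) is substituted by /j/, in onset and coda alike.
#'
#' @inheritParams apply_fronting
#' @return As [apply_fronting()].
#' @export
apply_r_weakening <- function(t, rules) {
  check_language(t, rules)
  map <- stats::setNames(as.list(rep(rules$r_weakening$target,
                                     length(rules$r_weakening$rhotics))),
                         rules$r_weakening$rhotics)
  apply_substitution_map(t, map, rules$inventory)
}

#' Simulate weak (pre-tonic) syllable deletion
#'
#' If a syllable carrying primary stress or a tonal accent exists and is
#' not word-initial, the single syllable immediately preceding it is
#' deleted; all its segments are recorded as deletions. Monosyllables
#' and initial-stress words are returned unchanged.
#'
#' @inheritParams apply_fronting
#' @return As [apply_fronting()].
#' @examples
#' r <- pattern_rules("eng")
#' apply_weak_syllable_deletion(parse_transcription("b@$\"n{$n@", "eng"), r)$t$raw
#' @export
apply_weak_syllable_deletion <- function(t, rules) {
  check_language(t, rules)
  anchors <- which(t$prosody %in% rules$weak_syllable_deletion$anchors)
  if (length(anchors) == 0L || anchors[1] == 1L)
    return(list(t = t, edits = empty_edits()))
  victim <- anchors[1] - 1L
  segs <- t$segments
  ord <- consonant_ordinal(segs)
  drop <- segs$syllable == victim
  edits <- edit_row("delete", ord[drop], segs$symbol[drop],
                    NA_character_, segs$is_consonant[drop])
  t$segments <- segs[!drop, ]
  list(t = rebuild_transcription(t), edits = edits)
}

#' Simulate cluster reduction
#'
#' Every syllable onset of two or more consonants is reduced to a single
#' member by the language's retention table: three-member onsets keep
#' the second consonant; /s/-initial two-member onsets keep the second
#' (with the English-specific exception /sl/ keeping the /s/); all other
#' two-member onsets keep the first. Codas are untouched. Onsets longer
#' than three consonants have no retention rule: they are left unchanged
#' and counted in the `unmatched` attribute of the edit record.
#'
#' @inheritParams apply_fronting
#' @return As [apply_fronting()]; the edit record carries an integer
#'   attribute `unmatched` with the number of onsets no rule covered.
#' @export
apply_cluster_reduction <- function(t, rules) {
  check_language(t, rules)
  cfg <- rules$cluster_reduction
  segs <- t$segments
  ord <- consonant_ordinal(segs)
  del <- logical(nrow(segs))
  edits <- empty_edits()
  unmatched <- 0L
  for (s in unique(segs$syllable)) {
    onset <- which(segs$syllable == s & segs$role == "onset")
    n <- length(onset)
    if (n < 2L) next
    key <- paste(segs$symbol[onset], collapse = "")
    if (!is.null(cfg$exceptions[[key]])) {
      keep <- as.integer(cfg$exceptions[[key]])
    } else if (n == 2L) {
      keep <- if (segs$symbol[onset[1]] %in% cfg$s_onsets) 2L else 1L
    } else if (n == 3L) {
      keep <- as.integer(cfg$keep_ccc)
    } else {
      unmatched <- unmatched + 1L
      next
    }
    gone <- onset[-keep]
    del[gone] <- TRUE
    edits <- rbind(edits, edit_row("delete", ord[gone], segs$symbol[gone],
                                   NA_character_, TRUE))
  }
  t$segments <- segs[!del, ]
  out <- list(t = rebuild_transcription(t), edits = edits)
  attr(out$edits, "unmatched") <- unmatched
  out
}

#' Apply one error pattern by name
#'
#' Dispatches to the six pattern simulators. Patterns are applied one at
#' a time and across the board (every applicable token in the word);
#' they are never composed.
#'
#' @param t A `phonsim_transcription`.
#' @param pattern One of [pattern_names()].
#' @param rules A [pattern_rules()] object; defaults to the bundled
#'   rules of the transcription's language.
#' @return List with `t` (transformed transcription) and `edits`.
#' @export
apply_pattern <- function(t, pattern, rules = pattern_rules(t$language)) {
  fn <- switch(pattern,
    fronting = apply_fronting,
    backing = apply_backing,
    stopping = apply_stopping,
    r_weakening = apply_r_weakening,
    weak_syllable_deletion = apply_weak_syllable_deletion,
    cluster_reduction = apply_cluster_reduction,
    stop("unknown pattern '", pattern, "'; expected one of: ",
         paste(pattern_names(), collapse = ", "))
  )
  fn(t, rules)
}
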
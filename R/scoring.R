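#' Load a metric scoring configuration
#'
#' The scoring configuration holds the point tables for the two
#' structural complexity measures. The IPC table awards points per
#' singleton (non-cluster) fricative/affricate, per dorsal consonant,
#' per onset/coda cluster, and a bonus per heterorganic cluster; the
#' symbols listed under `excluded` (the language's rhotic and /j/) earn
#' no points and contribute no place of articulation to the
#' heterorganicity decision. The WCM table awards points for long words
#' (three or more syllables), non-initial primary stress/accent, a
#' word-final consonant, each consonant cluster, and the velar, liquid
#' and fricative/affricate sound classes, with an extra point for
#' voiced fricatives/affricates.
#'
#' @param language Bundled language code or path to a scoring YAML file.
#' @return Object of class `phonsim_scoring`.
#' @export
load_scoring <- function(language) {
  cfg <- yaml::read_yaml(resolve_config_path(language, "scoring"))
  cfg$ipc$excluded <- as.character(cfg$ipc$excluded)
  cfg$wcm$velar_symbols <- as.character(cfg$wcm$velar_symbols)
  cfg$wcm$liquid_manners <- as.character(cfg$wcm$liquid_manners)
  class(cfg) <- "phonsim_scoring"
  cfg
}

#' @export
print.phonsim_scoring <- function(x, ...) {
  cat(sprintf("<phonsim_scoring> %s (IPC excluded: %s)\n", x$language,
              paste(x$ipc$excluded, collapse = ", ")))
  invisible(x)
}

# onset/coda consonant runs of length >= 2, as a list of row-index vectors
cluster_members <- function(segments) {
  out <- list()
  for (s in unique(segments$syllable)) {
    for (role in c("onset", "coda")) {
      idx <- which(segments$syllable == s & segments$role == role &
                     segments$is_consonant)
      if (length(idx) >= 2L) out[[length(out) + 1L]] <- idx
    }
  }
  out
}

#' Index of Phonetic Complexity (IPC)
#'
#' Additive complexity points over sound classes and structures; higher
#' scores mark words that are articulatorily more demanding. With the
#' default table: one point per singleton fricative/affricate, per
#' dorsal consonant, per consonant cluster, plus a bonus per
#' heterorganic cluster (members spanning two or more places of
#' articulation). Excluded symbols (rhotic, glide) score nothing.
#'
#' @param t A `phonsim_transcription`.
#' @param scoring A [load_scoring()] configuration; defaults to the
#'   bundled table for the transcription's language.
#' @return IPC points (numeric).
#' @examples
#' ipc_score(parse_transcription("\"\"g0$bar", "swe"))  # 1 (dorsal /g/)
#' ipc_score(parse_transcription("\"\"sp2:$ket", "swe"))  # 3
#' @export
ipc_score <- function(t, scoring = load_scoring(t$language)) {
  stopifnot(inherits(t, "phonsim_transcription"))
  pts <- scoring$ipc$points
  segs <- t$segments
  scored <- segs$is_consonant & !(segs$symbol %in% scoring$ipc$excluded)
  clusters <- cluster_members(segs)
  in_cluster <- logical(nrow(segs))
  for (cl in clusters) in_cluster[cl] <- TRUE
  fric <- scored & !in_cluster & segs$manner %in% c("fricative", "affricate")
  dorsal <- scored & segs$place %in% "dorsal"
  score <- sum(fric) * pts$singleton_fricative + sum(dorsal) * pts$dorsal +
    length(clusters) * pts$cluster
  for (cl in clusters) {
    places <- unique(segs$place[cl][scored[cl]])
    if (length(places) >= 2L) score <- score + pts$heterorganic
  }
  score
}

#' Word Complexity Measure (WCM)
#'
#' Additive points for word patterns (three or more syllables;
#' primary stress or accent on a non-initial syllable), syllable
#' structures (word-final consonant; each consonant cluster) and sound
#' classes (velars; liquids; fricatives/affricates, doubled when
#' voiced). The Swedish adaptation classifies /j/ as a voiced fricative
#' (2 points), so /r/ -> /j/ *increases* complexity in Swedish and
#' Norwegian while decreasing it in English, where /j/ is an unscored
#' approximant.
#'
#' @inheritParams ipc_score
#' @return WCM points (numeric).
#' @export
wcm_score <- function(t, scoring = load_scoring(t$language)) {
  stopifnot(inherits(t, "phonsim_transcription"))
  pts <- scoring$wcm$points
  segs <- t$segments
  score <- 0
  if (length(t$prosody) >= 3L) score <- score + pts$long_word
  anchors <- which(t$prosody %in% c("primary", "accent2"))
  if (length(anchors) && anchors[1] > 1L) score <- score + pts$noninitial_stress
  if (nrow(segs) && segs$is_consonant[nrow(segs)])
    score <- score + pts$final_consonant
  score <- score + length(cluster_members(segs)) * pts$cluster
  cons <- segs[segs$is_consonant, ]
  score <- score + sum(cons$symbol %in% scoring$wcm$velar_symbols) * pts$velar
  score <- score + sum(cons$manner %in% scoring$wcm$liquid_manners) * pts$liquid
  fric <- cons$manner %in% c("fricative", "affricate")
  score <- score + sum(fric) * pts$fricative +
    sum(fric & cons$voiced) * pts$voiced_fricative
  score
}

#' Structural complexity difference between two forms
#'
#' IPC and WCM of the "misarticulated" form minus the original form:
#' negative values mark a reduction in phonological complexity,
#' positive values an increase (as with backing, which replaces early
#' acquired coronals with later acquired velars).
#'
#' @param orig,err `phonsim_transcription`s of the same language.
#' @param scoring A [load_scoring()] configuration.
#' @return Named numeric vector `c(ipc = ..., wcm = ...)`.
#' @export
structural_diff <- function(orig, err, scoring = load_scoring(orig$language)) {
  if (!identical(orig$language, err$language))
    stop("transcriptions are from different languages")
  c(ipc = ipc_score(err, scoring) - ipc_score(orig, scoring),
    wcm = wcm_score(err, scoring) - wcm_score(orig, scoring))
}
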
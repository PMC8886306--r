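#' Parse a SAMPA transcription
#'
#' Splits a raw SAMPA string into syllables on the `$` delimiter,
#' captures a leading stress/accent marker of each syllable as its
#' prosody (`"` primary stress, `""` accent 2, `%` secondary stress),
#' tokenizes the remainder greedily against the inventory (longest
#' symbols first), folds the length marker `:` into the preceding
#' segment, and assigns onset/nucleus/coda roles: consonants before the
#' first vowel form the onset, consonants after the last vowel the
#' coda.
#'
#' @param raw Non-empty SAMPA string, e.g. `"\"\"sp2:$ket"`.
#' @param inventory A [load_inventory()] object, or a language code.
#' @param lenient If `TRUE`, vowel-less syllables (interjections like
#'   "hm") are accepted, all their segments treated as onset. The
#'   default rejects them, since the metrics assume a syllable nucleus.
#' @return An object of class `phonsim_transcription`: list with `raw`,
#'   `language`, `prosody` (one of `"none"`, `"primary"`, `"accent2"`,
#'   `"secondary"` per syllable) and `segments`, a data frame with one
#'   row per segment (columns `syllable`, `role`, `symbol`, `long`,
#'   `is_consonant`, `place`, `manner`, `voiced`).
#' @examples
#' t <- parse_transcription("\"\"sp2:$ket", "swe")
#' nchar(t$raw)            # 10 characters, markers included
#' n_segments(t)           # 6 segments (2: is one long vowel)
#' consonant_tokens(t)$symbol
#' @seealso [serialize_transcription()], [consonant_tokens()]
#' @export
parse_transcription <- function(raw, inventory, lenient = FALSE) {
  if (!is_inventory(inventory)) inventory <- load_inventory(inventory)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("'raw' must be a single non-empty string")
  mk <- inventory$markers
  parts <- strsplit(raw, mk$syllable, fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts)))
    stop("empty syllable in '", raw, "'")

  seg_rows <- vector("list", length(parts))
  prosody <- character(length(parts))
  offset <- 0L
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (startsWith(p, mk$accent2)) {
      prosody[i] <- "accent2"; p <- substring(p, nchar(mk$accent2) + 1L)
    } else if (startsWith(p, mk$primary)) {
      prosody[i] <- "primary"; p <- substring(p, nchar(mk$primary) + 1L)
    } else if (startsWith(p, mk$secondary)) {
      prosody[i] <- "secondary"; p <- substring(p, nchar(mk$secondary) + 1L)
    } else prosody[i] <- "none"
    toks <- tokenize_syllable(p, inventory, raw, offset + nchar(parts[i]) - nchar(p))
    segs <- segment_features(toks$symbol, inventory)
    segs$long <- toks$long
    if (!nzchar(p) || nrow(segs) == 0L) stop("empty syllable in '", raw, "'")
    vpos <- which(!segs$is_consonant)
    if (length(vpos) == 0L) {
      if (!lenient)
        stop("syllable '", parts[i], "' in '", raw, "' has no vowel ",
             "(use lenient = TRUE to accept)")
      segs$role <- "onset"
    } else {
      segs$role <- "nucleus"
      if (vpos[1] > 1L) segs$role[seq_len(vpos[1] - 1L)] <- "onset"
      lastv <- vpos[length(vpos)]
      if (lastv < nrow(segs)) segs$role[(lastv + 1L):nrow(segs)] <- "coda"
      inner <- segs$is_consonant & segs$role == "nucleus"
      if (any(inner))
        stop("consonant '", segs$symbol[which(inner)[1]],
             "' between vowels within one syllable in '", raw, "'")
    }
    segs$syllable <- i
    seg_rows[[i]] <- segs
    offset <- offset + nchar(parts[i]) + nchar(mk$syllable)
  }
  segments <- do.call(rbind, seg_rows)
  segments <- segments[, c("syllable", "role", "symbol", "long",
                           "is_consonant", "place", "manner", "voiced")]
  rownames(segments) <- NULL
  t <- list(raw = raw, language = inventory$language,
            prosody = prosody, segments = segments)
  class(t) <- "phonsim_transcription"
  t
}

# greedy longest-match tokenization of one syllable body (marker already
# stripped); the length marker attaches to the preceding symbol
tokenize_syllable <- function(p, inventory, raw, offset) {
  symbols <- inventory$symbols
  len_mk <- inventory$markers$length
  out_sym <- character(0)
  out_long <- logical(0)
  pos <- 1L
  n <- nchar(p)
  while (pos <= n) {
    rest <- substring(p, pos)
    if (startsWith(rest, len_mk)) {
      if (length(out_sym) == 0L)
        stop("length marker with no preceding segment at position ",
             offset + pos, " in '", raw, "'")
      out_long[length(out_long)] <- TRUE
      pos <- pos + nchar(len_mk)
      next
    }
    hit <- symbols[startsWith(rest, symbols)][1]
    if (is.na(hit))
      stop("unknown symbol '", substring(rest, 1, 1), "' at position ",
           offset + pos, " in '", raw, "'")
    out_sym <- c(out_sym, hit)
    out_long <- c(out_long, FALSE)
    pos <- pos + nchar(hit)
  }
  list(symbol = out_sym, long = out_long)
}

#' Serialize a transcription back to its SAMPA string
#'
#' Inverse of [parse_transcription()]: prosody markers are re-attached
#' to their syllables, long segments regain the length marker, and
#' syllables are joined with the delimiter. `serialize_transcription(
#' parse_transcription(x, inv))` is the identity on valid input.
#'
#' @param t A `phonsim_transcription`.
#' @param markers Marker conventions; defaults to the ones of the
#'   bundled inventories.
#' @return SAMPA string.
#' @export
serialize_transcription <- function(t, markers = NULL) {
  stopifnot(inherits(t, "phonsim_transcription"))
  if (is.null(markers))
    markers <- list(primary = "\"", accent2 = "\"\"", secondary = "%",
                    syllable = "$", length = ":")
  pref <- c(none = "", primary = markers$primary,
            accent2 = markers$accent2, secondary = markers$secondary)
  segs <- t$segments
  body <- vapply(seq_along(t$prosody), function(i) {
    s <- segs[segs$syllable == i, ]
    paste0(s$symbol, ifelse(s$long, markers$length, ""), collapse = "")
  }, character(1))
  paste0(pref[t$prosody], body, collapse = markers$syllable)
}

# rebuild a transcription object after segment-level edits
rebuild_transcription <- function(t) {
  keep <- sort(unique(t$segments$syllable))
  t$segments$syllable <- match(t$segments$syllable, keep)
  t$prosody <- t$prosody[keep]
  rownames(t$segments) <- NULL
  t$raw <- serialize_transcription(t)
  t
}

#' Consonant tokens of a transcription
#'
#' Consonants in left-to-right word order, clusters flattened. The row
#' count is the "n consonants" denominator of PCC and pMLU.
#'
#' @param t A `phonsim_transcription`.
#' @return Data frame of consonant segments (subset of `t$segments`).
#' @export
consonant_tokens <- function(t) {
  stopifnot(inherits(t, "phonsim_transcription"))
  out <- t$segments[t$segments$is_consonant, ]
  rownames(out) <- NULL
  out
}

#' Number of segments in a transcription
#'
#' Long vowels/consonants and multi-character symbols (affricates,
#' diphthongs, retroflexes) count as one segment; prosodic markers and
#' delimiters count as none.
#'
#' @param t A `phonsim_transcription`.
#' @return Integer segment count.
#' @export
n_segments <- function(t) {
  stopifnot(inherits(t, "phonsim_transcription"))
  nrow(t$segments)
}

#' @export
print.phonsim_transcription <- function(x, ...) {
  cat(sprintf("<phonsim_transcription> /%s/ (%s): %d syllable(s), %d segment(s)\n",
              x$raw, x$language, length(x$prosody), nrow(x$segments)))
  invisible(x)
}

#' @export
format.phonsim_transcription <- function(x, ...) x$raw
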
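#' Read a unigram frequency list
#'
#' Expects UTF-8 TSV with two fields per line, `word<TAB>count`. Words
#' are case-folded; counts of duplicate words are summed.
#'
#' @param path File path.
#' @return Data frame with columns `word`, `count` and attribute
#'   `source_label` (the file name).
#' @export
read_frequency_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed frequency list line ", bad[1], " in '", path,
         "': expected 'word<TAB>count'")
  counts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(counts) || any(counts < 1) || any(counts != round(counts)))
    stop("malformed count on line ",
         which(is.na(counts) | counts < 1 | counts != round(counts))[1],
         " in '", path, "'")
  fl <- frequency_list(vapply(parts, `[[`, "", 1L), as.integer(counts))
  attr(fl, "source_label") <- basename(path)
  fl
}

# construct a case-folded, duplicate-summed frequency list
frequency_list <- function(word, count) {
  word <- tolower(word)
  agg <- tapply(count, word, sum)
  out <- data.frame(word = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$word), ]
  rownames(out) <- NULL
  out
}

#' Write a frequency list as TSV
#'
#' @param fl Frequency list data frame (`word`, `count`).
#' @param path Output path.
#' @export
write_frequency_list <- function(fl, path) {
  utils::write.table(fl[, c("word", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop hapax legomena from a frequency list
#'
#' Words occurring exactly once in the corpus are excluded before any
#' analysis.
#'
#' @param fl Frequency list data frame.
#' @return The filtered frequency list (counts >= 2).
#' @export
exclude_hapax <- function(fl) {
  out <- fl[fl$count >= 2L, , drop = FALSE]
  if (nrow(out) == 0L) warning("all words are hapax legomena; empty list returned")
  rownames(out) <- NULL
  out
}

#' Remove closed-class words from a frequency list
#'
#' Structural measures (IPC, WCM, PWP) are aggregated over open-class
#' words only; the purely relational measures (PCC, LVN) use all
#' tokens. [aggregate_effects()] applies this split internally --- this
#' helper is the standalone filter.
#'
#' @param fl Frequency list data frame.
#' @param closed_class Character vector of closed-class words.
#' @return Frequency list without the listed words.
#' @export
filter_closed_class <- function(fl, closed_class) {
  out <- fl[!(fl$word %in% tolower(closed_class)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most frequent word types
#'
#' Emits the top of a frequency list as candidates for manual
#' closed-class curation.
#'
#' @param fl Frequency list data frame.
#' @param n Number of candidates.
#' @return Character vector of at most `n` words, most frequent first.
#' @export
top_frequent <- function(fl, n = 100L) {
  utils::head(fl$word[order(-fl$count)], n)
}

#' Read a pronunciation lexicon
#'
#' UTF-8 TSV `word<TAB>sampa`; when a word repeats, the first entry
#' wins (one transcription per word).
#'
#' @param path File path.
#' @return Named character vector mapping case-folded word to SAMPA.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed lexicon line ", bad[1], " in '", path,
         "': expected 'word<TAB>sampa'")
  word <- tolower(vapply(parts, `[[`, "", 1L))
  sampa <- vapply(parts, `[[`, "", 2L)
  keep <- !duplicated(word)
  stats::setNames(sampa[keep], word[keep])
}

#' Read a one-word-per-line list
#'
#' @param path File path (e.g. a closed-class word list).
#' @return Character vector, case-folded.
#' @export
read_word_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tolower(trimws(x[nzchar(trimws(x))]))
}

# token-weighted mean / population SD / SEM
weighted_stats <- function(x, w) {
  W <- sum(w)
  if (W == 0) return(c(mean = NA_real_, sd = NA_real_, sem = NA_real_,
                       n_tokens = 0, n_types = 0))
  m <- sum(w * x) / W
  sd <- sqrt(sum(w * (x - m)^2) / W)
  c(mean = m, sd = sd, sem = sd / sqrt(W), n_tokens = W, n_types = length(x))
}

#' Aggregate the phonological effect of one pattern over a corpus
#'
#' Scores every word type of the frequency list that has a lexicon
#' entry, then aggregates each metric across word *tokens*: each type
#' contributes with its token count as weight, so the token-weighted
#' mean equals the plain mean over the corpus expanded token by token.
#' SD uses the population formula; SEM = SD / sqrt(n_tokens).
#'
#' Aggregation pathways differ by measure: the structural and combined
#' measures (IPC diff, WCM diff, PWP) run over open-class tokens only,
#' the purely relational measures (PCC, LVN) over all tokens. Words
#' without a lexicon entry or that fail to parse are skipped and
#' counted; words without consonants are excluded from the PCC.
#'
#' @param pattern One of [pattern_names()].
#' @param fl Frequency list data frame (see [read_frequency_list()];
#'   hapax exclusion is the caller's step, see [exclude_hapax()]).
#' @param lexicon Named character vector word -> SAMPA
#'   ([read_lexicon()]).
#' @param language Language code.
#' @param closed_class Character vector of closed-class words.
#' @param scoring,rules Configurations; default to the language's
#'   bundled ones.
#' @param applicable_only If `TRUE`, only words where the pattern
#'   actually applied (at least one edit) enter the aggregation --- a
#'   sensitivity analysis; the default keeps unaffected words (effect
#'   0 / PCC 100), matching near-ceiling corpus PCC values.
#' @param corpus_label Label carried into the report.
#' @return Object of class `phonsim_report`: list with `pattern`,
#'   `corpus_label`, `metrics` (data frame: metric, mean, sd, sem,
#'   n_tokens, n_types), `diagnostics` and `scores` (the per-type
#'   [score_word()] rows with token counts).
#' @export
aggregate_effects <- function(pattern, fl, lexicon, language,
                              closed_class = character(0),
                              scoring = load_scoring(language),
                              rules = pattern_rules(language),
                              applicable_only = FALSE,
                              corpus_label = attr(fl, "source_label") %||% "") {
  stopifnot(pattern %in% pattern_names())
  closed_class <- tolower(closed_class)
  has_trsc <- fl$word %in% names(lexicon)
  n_skipped <- sum(!has_trsc)
  types <- fl[has_trsc, , drop = FALSE]
  if (nrow(types) == 0L) stop("no word of the frequency list has a lexicon entry")

  rows <- vector("list", nrow(types))
  unmatched <- 0L
  parse_failed <- character(0)
  for (i in seq_len(nrow(types))) {
    w <- types$word[i]
    t <- tryCatch(parse_transcription(lexicon[[w]], rules$inventory),
                  error = function(e) NULL)
    if (is.null(t)) { parse_failed <- c(parse_failed, w); next }
    res <- apply_pattern(t, pattern, rules)
    unmatched <- unmatched + (attr(res$edits, "unmatched") %||% 0L)
    err <- res$t
    sc <- score_word(w, t, pattern, language, scoring, rules)
    sc$count <- types$count[i]
    rows[[i]] <- sc
  }
  scores <- do.call(rbind, rows)
  n_skipped <- n_skipped + length(parse_failed)
  if (is.null(scores) || nrow(scores) == 0L)
    stop("no word of the frequency list could be scored")
  if (applicable_only) scores <- scores[scores$n_edits > 0L, , drop = FALSE]

  open <- scores[!(scores$word %in% closed_class), , drop = FALSE]
  with_cons <- scores[!is.na(scores$pcc), , drop = FALSE]
  metrics <- rbind(
    ipc = weighted_stats(open$ipc_diff, open$count),
    wcm = weighted_stats(open$wcm_diff, open$count),
    pwp = weighted_stats(open$pwp, open$count),
    pcc = weighted_stats(with_cons$pcc, with_cons$count),
    lvn = weighted_stats(scores$lvn, scores$count)
  )
  metrics <- data.frame(metric = rownames(metrics), metrics,
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- list(
    pattern = pattern, corpus_label = corpus_label, metrics = metrics,
    diagnostics = list(
      n_skipped_no_transcription = n_skipped,
      n_zero_consonant = sum(is.na(scores$pcc)),
      n_unmatched_clusters = unmatched,
      parse_failed = parse_failed
    ),
    scores = scores
  )
  class(out) <- "phonsim_report"
  out
}

#' @export
print.phonsim_report <- function(x, ...) {
  cat(sprintf("<phonsim_report> pattern '%s'%s\n", x$pattern,
              if (nzchar(x$corpus_label)) paste0(" on ", x$corpus_label) else ""))
  print(x$metrics, digits = 4)
  d <- x$diagnostics
  cat(sprintf("skipped (no transcription): %d; zero-consonant: %d; unmatched clusters: %d\n",
              d$n_skipped_no_transcription, d$n_zero_consonant,
              d$n_unmatched_clusters))
  invisible(x)
}

#' Effect table across all six patterns
#'
#' Runs [aggregate_effects()] for every pattern and collects the
#' token-weighted means into one data frame, one row per pattern ---
#' the shape used for rank analysis against clinician ratings.
#'
#' @inheritParams aggregate_effects
#' @param patterns Patterns to include.
#' @return Data frame with columns `pattern`, `ipc`, `wcm`, `pcc`,
#'   `lvn`, `pwp` (token-weighted means).
#' @export
effect_table <- function(fl, lexicon, language,
                         closed_class = character(0),
                         patterns = pattern_names(), ...) {
  rows <- lapply(patterns, function(p) {
    rep <- aggregate_effects(p, fl, lexicon, language, closed_class, ...)
    m <- stats::setNames(rep$metrics$mean, rep$metrics$metric)
    data.frame(pattern = p, ipc = m[["ipc"]], wcm = m[["wcm"]],
               pcc = m[["pcc"]], lvn = m[["lvn"]], pwp = m[["pwp"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
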
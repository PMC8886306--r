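# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# textbook dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  }
  d[n + 1, m + 1]
}

# build a random inventory-valid SAMPA string by direct concatenation
# of symbols from the inventory tables (no use of the parser)
random_sampa <- function(inv, max_syll = 3L) {
  cons <- inv$consonants$symbol
  vows <- inv$vowels
  mk <- inv$markers
  nsyl <- sample.int(max_syll, 1L)
  stressed <- sample.int(nsyl, 1L)
  syls <- vapply(seq_len(nsyl), function(s) {
    marker <- if (s == stressed)
      sample(c(mk$primary, mk$accent2, mk$secondary, ""), 1L) else ""
    onset <- paste(sample(cons, sample(0:2, 1L)), collapse = "")
    nucleus <- paste0(sample(vows, 1L),
                      if (stats::runif(1) < 0.3) mk$length else "")
    coda <- paste(sample(cons, sample(0:2, 1L)), collapse = "")
    paste0(marker, onset, nucleus, coda)
  }, character(1))
  paste(syls, collapse = mk$syllable)
}

# regex-based consonant counter: strips markers/delimiters, then eats
# inventory symbols longest-first, counting consonant matches
regex_consonant_count <- function(raw, inv) {
  body <- gsub("[\"%$:]", "", raw)
  syms <- c(inv$consonants$symbol, inv$vowels)
  syms <- syms[order(-nchar(syms))]
  n <- 0L
  while (nzchar(body)) {
    hit <- syms[startsWith(body, syms)][1]
    stopifnot(!is.na(hit))
    if (hit %in% inv$consonants$symbol) n <- n + 1L
    body <- substring(body, nchar(hit) + 1L)
  }
  n
}

fixture_report <- function(pattern, language = "swe", seed = 11L, ...) {
  fx <- generate_lexicon(fixture_spec(language, seed = seed, ...))
  aggregate_effects(pattern, fx$freq, fx$lexicon, language)
}
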
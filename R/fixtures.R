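#' Specification for a synthetic lexicon
#'
#' The generator emulates the corpus properties that drive pattern
#' effects --- how often onsets are clusters, how often consonants are
#' fricatives, velars or rhotics, and how often stress falls on a
#' non-initial syllable (giving weak syllable deletion a pre-tonic
#' target) --- with Zipf-like token counts. Same seed, same output.
#'
#' @param language Language code (`"swe"`, `"nor"`, `"eng"`).
#' @param n_types Number of word types.
#' @param zipf_exponent Exponent of the Zipf-like count decay.
#' @param p_onset_cluster Probability that a syllable onset is a
#'   two-consonant cluster.
#' @param p_fricative,p_velar,p_rhotic Probabilities that a singleton
#'   onset consonant is drawn from the fricative, velar-plosive or
#'   rhotic pool (must sum to < 1; the rest comes from a plain pool of
#'   early consonants).
#' @param p_pretonic Probability that a polysyllabic word is stressed
#'   on its second syllable (leaving a pre-tonic first syllable).
#' @param syllables_range Integer `c(min, max)` syllables per word.
#' @param p_coda Probability of a single-consonant coda.
#' @param n_hapax Number of injected hapax rows (count 1), so hapax
#'   filtering is exercised deliberately rather than by chance.
#' @param seed Integer seed; generation is deterministic given it.
#' @return Object of class `phonsim_fixture_spec`.
#' @export
fixture_spec <- function(language = "swe", n_types = 60L,
                         zipf_exponent = 1.1, p_onset_cluster = 0.2,
                         p_fricative = 0.25, p_velar = 0.15,
                         p_rhotic = 0.1, p_pretonic = 0.25,
                         syllables_range = c(1L, 3L), p_coda = 0.4,
                         n_hapax = 0L, seed = 1L) {
  probs <- c(p_onset_cluster, p_fricative, p_velar, p_rhotic, p_pretonic, p_coda)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_fricative + p_velar + p_rhotic > 1)
    stop("p_fricative + p_velar + p_rhotic must not exceed 1")
  if (n_types < 1L) stop("'n_types' must be >= 1")
  if (length(syllables_range) != 2L || syllables_range[1] < 1L ||
      syllables_range[2] < syllables_range[1])
    stop("'syllables_range' must be c(min, max) with 1 <= min <= max")
  spec <- list(language = language, n_types = as.integer(n_types),
               zipf_exponent = zipf_exponent,
               p_onset_cluster = p_onset_cluster, p_fricative = p_fricative,
               p_velar = p_velar, p_rhotic = p_rhotic,
               p_pretonic = p_pretonic,
               syllables_range = as.integer(syllables_range),
               p_coda = p_coda, n_hapax = as.integer(n_hapax),
               seed = as.integer(seed))
  class(spec) <- "phonsim_fixture_spec"
  spec
}

# run expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic lexicon and frequency list
#'
#' Builds `n_types` inventory-valid SAMPA words following the
#' language's C0-3 V C0-1 syllable templates and the structure
#' probabilities of the spec, plus Zipf-like token counts (floored at
#' 2; hapax rows only by explicit injection). Every generated word
#' parses against the inventory by construction.
#'
#' @param spec A [fixture_spec()].
#' @return List with `freq` (frequency list data frame), `lexicon`
#'   (named character vector word -> SAMPA) and `closed_class` (empty
#'   placeholder vector; closed-class curation is manual by design).
#' @examples
#' fx <- generate_lexicon(fixture_spec("swe", n_types = 10, seed = 42))
#' head(fx$freq)
#' @export
generate_lexicon <- function(spec) {
  stopifnot(inherits(spec, "phonsim_fixture_spec"))
  inv <- load_inventory(spec$language)
  cons <- inv$consonants
  pool <- list(
    fricative = cons$symbol[cons$manner %in% c("fricative", "affricate") &
                              cons$symbol != "h"],
    velar = cons$symbol[cons$place == "dorsal" & cons$manner == "plosive"],
    rhotic = intersect(c("r", "r'"), cons$symbol),
    plain = intersect(c("p", "b", "t", "d", "m", "n", "l"), cons$symbol),
    coda = intersect(c("p", "t", "k", "m", "n", "s", "l"), cons$symbol),
    cluster = c(lapply(intersect(c("p", "t", "k"), cons$symbol),
                       function(c2) c("s", c2)),
                lapply(intersect(c("p", "b", "k", "g", "f"), cons$symbol),
                       function(c1) c(c1, intersect(c("r", "l"), cons$symbol)[1]))),
    vowel = inv$vowels[nchar(inv$vowels) == 1L & inv$vowels != "@"]
  )
  pick <- function(x) x[sample.int(length(x), 1L)]

  with_seed(spec$seed, {
    n_all <- spec$n_types + spec$n_hapax
    words <- character(n_all); sampa <- character(n_all)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n_all)) {
      repeat {
        nsyl <- sample(seq(spec$syllables_range[1], spec$syllables_range[2]), 1L)
        stressed <- if (nsyl >= 2L && stats::runif(1) < spec$p_pretonic) 2L else 1L
        syls <- vapply(seq_len(nsyl), function(s) {
          if (stats::runif(1) < spec$p_onset_cluster) {
            onset <- paste(pool$cluster[[sample.int(length(pool$cluster), 1L)]],
                           collapse = "")
          } else {
            u <- stats::runif(1)
            src <- if (u < spec$p_fricative) pool$fricative
            else if (u < spec$p_fricative + spec$p_velar) pool$velar
            else if (u < spec$p_fricative + spec$p_velar + spec$p_rhotic &&
                       length(pool$rhotic)) pool$rhotic
            else pool$plain
            onset <- pick(src)
          }
          nucleus <- paste0(pick(pool$vowel),
                            if (stats::runif(1) < 0.35) inv$markers$length else "")
          coda <- if (stats::runif(1) < spec$p_coda) pick(pool$coda) else ""
          paste0(if (s == stressed) inv$markers$primary else "",
                 onset, nucleus, coda)
        }, character(1))
        raw <- paste(syls, collapse = inv$markers$syllable)
        key <- tolower(gsub("[^a-z]", "", raw))
        word <- paste0(if (nzchar(key)) key else "w", i)
        if (is.null(seen[[word]])) { assign(word, TRUE, envir = seen); break }
      }
      words[i] <- word; sampa[i] <- raw
    }
    count <- pmax(2L, as.integer(round(200 / seq_len(spec$n_types)^spec$zipf_exponent)))
    if (spec$n_hapax > 0L) count <- c(count, rep(1L, spec$n_hapax))
    freq <- data.frame(word = words, count = count, stringsAsFactors = FALSE)
    attr(freq, "source_label") <- sprintf("synthetic-%s-seed%d",
                                          spec$language, spec$seed)
    list(freq = freq, lexicon = stats::setNames(sampa, words),
         closed_class = character(0))
  })
}

#' Write fixture files to a directory
#'
#' Emits `freq.tsv`, `lexicon.tsv` and `closed_class.txt` in the
#' formats the corpus pipeline reads.
#'
#' @param fx Output of [generate_lexicon()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frequency_list(fx$freq, file.path(dir, "freq.tsv"))
  utils::write.table(
    data.frame(names(fx$lexicon), unname(fx$lexicon)),
    file.path(dir, "lexicon.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  writeLines(fx$closed_class, file.path(dir, "closed_class.txt"))
  invisible(dir)
}

#' Worked stopping example: Swedish "spöket"
#'
#' The Swedish word "spöket" (SAMPA `""sp2:$ket`, accent 2) under
#' stopping: the cluster-internal /s/ is deleted, giving `""p2:$ket`.
#' The bundle carries the expected metric values for regression tests:
#' IPC 3 -> 1 (diff -2), WCM diff -2, PCC 75, LVN 1/19, pMLU 10 -> 8,
#' PWP 0.8.
#'
#' @return List with `word`, `language`, `orig`, `pattern` and
#'   `expected` (named list of the values above).
#' @export
spoket_example <- function() {
  list(
    word = "spöket", language = "swe", orig = "\"\"sp2:$ket",
    pattern = "stopping",
    expected = list(
      err = "\"\"p2:$ket",
      ipc_orig = 3, ipc_err = 1, ipc_diff = -2,
      wcm_diff = -2,
      pcc = 75, lev = 1, lvn = 1 / 19,
      pmlu_orig = 10, pmlu_err = 8, pwp = 0.8
    )
  )
}
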
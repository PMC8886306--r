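#' Languages with bundled configuration
#'
#' @return Character vector of language codes for which the package ships
#'   a phoneme inventory, pattern rule tables and a scoring configuration.
#' @export
available_languages <- function() c("swe", "nor", "eng")

phonsim_file <- function(...) {
  path <- system.file("extdata", ..., package = "phonsim")
  if (!nzchar(path)) stop("bundled file not found: ", file.path(...), call. = FALSE)
  path
}

resolve_config_path <- function(x, subdir) {
  if (x %in% available_languages()) phonsim_file(subdir, paste0(x, ".yaml")) else x
}

#' Load a phoneme inventory
#'
#' An inventory is the per-language symbol table governing SAMPA
#' tokenization and feature classification: consonants with place
#' (labial, coronal, retroflex, dorsal, glottal), manner (plosive,
#' fricative, affricate, nasal, liquid, approximant, tap) and voicing;
#' vowels; and the prosodic marker conventions (primary stress `"`,
#' accent 2 `""`, secondary stress `%`, syllable delimiter `$`, length
#' `:`). Multi-character symbols (affricates, retroflexes, diphthongs)
#' are tokenized greedily, longest first.
#'
#' @param language A bundled language code (`"swe"`, `"nor"`, `"eng"`)
#'   or the path to an inventory YAML file with the same schema as the
#'   bundled ones (see `system.file("extdata", "inventories",
#'   package = "phonsim")`).
#' @return An object of class `phonsim_inventory`: a list with elements
#'   `language`, `name`, `consonants` (data frame: symbol, place,
#'   manner, voiced), `vowels`, `markers` and `symbols` (the greedy
#'   tokenization order).
#' @examples
#' inv <- load_inventory("swe")
#' inv$consonants[inv$consonants$place == "dorsal", ]
#' @export
load_inventory <- function(language) {
  cfg <- yaml::read_yaml(resolve_config_path(language, "inventories"))
  cons <- do.call(rbind, lapply(cfg$consonants, function(x) {
    data.frame(symbol = x$symbol, place = x$place, manner = x$manner,
               voiced = isTRUE(x$voiced), stringsAsFactors = FALSE)
  }))
  vowels <- as.character(cfg$vowels)
  if (anyDuplicated(c(cons$symbol, vowels)))
    stop("inventory symbols must be unique across consonants and vowels")
  places <- c("labial", "coronal", "retroflex", "dorsal", "glottal")
  manners <- c("plosive", "fricative", "affricate", "nasal", "liquid",
               "approximant", "tap")
  if (!all(cons$place %in% places)) stop("unknown place of articulation in inventory")
  if (!all(cons$manner %in% manners)) stop("unknown manner of articulation in inventory")
  symbols <- c(cons$symbol, vowels)
  inv <- list(
    language = cfg$language,
    name = cfg$name,
    consonants = cons,
    vowels = vowels,
    markers = cfg$markers,
    symbols = symbols[order(-nchar(symbols), symbols)]
  )
  class(inv) <- "phonsim_inventory"
  inv
}

#' @export
print.phonsim_inventory <- function(x, ...) {
  cat(sprintf("<phonsim_inventory> %s (%s): %d consonants, %d vowels\n",
              x$name, x$language, nrow(x$consonants), length(x$vowels)))
  invisible(x)
}

is_inventory <- function(x) inherits(x, "phonsim_inventory")

# feature lookup for a consonant or vowel symbol; vowels get NA
# place/manner and are treated as voiced
segment_features <- function(symbols, inv) {
  idx <- match(symbols, inv$consonants$symbol)
  is_cons <- !is.na(idx)
  data.frame(
    symbol = symbols,
    is_consonant = is_cons,
    place = ifelse(is_cons, inv$consonants$place[idx], NA_character_),
    manner = ifelse(is_cons, inv$consonants$manner[idx], NA_character_),
    voiced = ifelse(is_cons, inv$consonants$voiced[idx], TRUE),
    stringsAsFactors = FALSE
  )
}
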
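#' Preprocessing configuration
#'
#' Token normalization used throughout the package: strip a trailing
#' possessive \code{'s}, lowercase, strip a regular gerund suffix
#' (\code{-ing}) when enough stem remains, and strip a single plural
#' \code{-s} (but never a double \code{ss}).  Stopwords are removed after
#' normalization; only unigrams are kept, no phrase detection is attempted.
#'
#' @param stopwords character vector of lowercase stopwords.  Defaults to the
#'   English function-word list shipped with the package (see
#'   [default_stopwords()]).
#' @param gerund_min_stem_length smallest stem length (in characters) that a
#'   word must retain for its \code{-ing} suffix to be stripped; guards short
#'   words such as "ring" or "king".
#' @param apply_possessive_strip,apply_plural_strip,apply_gerund_strip toggle
#'   the individual normalization rules.
#' @return an object of class \code{preprocessing_config}.
#' @export
preprocessing_config <- function(stopwords = default_stopwords(),
                                 gerund_min_stem_length = 3L,
                                 apply_possessive_strip = TRUE,
                                 apply_plural_strip = TRUE,
                                 apply_gerund_strip = TRUE) {
  stopwords <- as.character(stopwords)
  if (length(stopwords) == 0L) {
    stop("stopword list must be non-empty")
  }
  gerund_min_stem_length <- as.integer(gerund_min_stem_length)
  if (is.na(gerund_min_stem_length) || gerund_min_stem_length < 1L) {
    stop("gerund_min_stem_length must be >= 1")
  }
  structure(
    list(
      stopwords = tolower(stopwords),
      gerund_min_stem_length = gerund_min_stem_length,
      apply_possessive_strip = isTRUE(apply_possessive_strip),
      apply_plural_strip = isTRUE(apply_plural_strip),
      apply_gerund_strip = isTRUE(apply_gerund_strip)
    ),
    class = "preprocessing_config"
  )
}

#' Default English stopword list
#'
#' Reads the one-term-per-line stopword file shipped under
#' \code{inst/extdata/stopwords_en.txt}: closed-class English function words
#' only, so domain terms are never removed.  Results depend on the stopword
#' list; to reproduce a run exactly, keep the list fixed.
#'
#' @param path optional path to an alternative one-term-per-line UTF-8 file.
#' @return character vector of lowercase stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "pbcouple")
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  tolower(words[nzchar(words)])
}

#' Normalize one word
#'
#' Applies, in order: possessive strip (\code{'s}), lowercasing, gerund strip
#' (\code{-ing} when the remaining stem has at least
#' \code{gerund_min_stem_length} characters), plural strip (one trailing
#' \code{s} unless the word ends in \code{ss}).  Total and deterministic on
#' non-empty strings; idempotent.
#'
#' @param raw_word a non-empty, whitespace-free string (vectorized).
#' @param config a [preprocessing_config()].
#' @return normalized token(s), possibly empty strings.
#' @examples
#' cfg <- preprocessing_config(stopwords = "the")
#' normalize_token("working", cfg)  # "work"
#' normalize_token("works", cfg)    # "work"
#' @export
normalize_token <- function(raw_word, config = preprocessing_config()) {
  w <- as.character(raw_word)
  if (config$apply_possessive_strip) {
    w <- sub("['’″]s$", "", w)
  }
  w <- tolower(w)
  # suffix rules are iterated to a fixpoint so that stacked suffixes
  # ("meetings" -> "meeting" -> "meet") normalize in one call and the
  # function is idempotent
  repeat {
    before <- w
    if (config$apply_gerund_strip) {
      is_ger <- grepl("ing$", w) &
        nchar(w) - 3L >= config$gerund_min_stem_length
      w[is_ger] <- sub("ing$", "", w[is_ger])
    }
    if (config$apply_plural_strip) {
      is_pl <- grepl("s$", w) & !grepl("ss$", w)
      w[is_pl] <- sub("s$", "", w[is_pl])
    }
    if (identical(w, before)) break
  }
  w
}

#' Preprocess raw text into the normalized token stream
#'
#' Splits on non-alphanumeric boundaries, normalizes every piece with
#' [normalize_token()], and drops stopwords and empty results.  A word is
#' treated as a stopword if either its lowercased surface form or its
#' normalized form is on the list (so inflected function words such as "has"
#' are still removed).  Output order follows input order; unigrams only.
#'
#' @param raw_text any string (possibly empty, possibly multi-element; elements
#'   are concatenated in order).
#' @param config a [preprocessing_config()].
#' @return character vector of normalized tokens (possibly empty).
#' @export
preprocess_text <- function(raw_text, config = preprocessing_config()) {
  raw_text <- paste(as.character(raw_text), collapse = " ")
  if (!nzchar(raw_text)) {
    return(character(0))
  }
  # possessive markers are handled by normalize_token; protect them from the
  # non-alphanumeric split so "gene's" yields one word, then split the rest
  pieces <- unlist(strsplit(raw_text, "[^[:alnum:]'’″]+"),
                   use.names = FALSE)
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L) {
    return(character(0))
  }
  norm <- normalize_token(pieces, config)
  # strip any apostrophes that survived normalization (e.g. internal quotes)
  norm <- gsub("['’″]", "", norm)
  keep <- nzchar(norm) &
    !(tolower(pieces) %in% config$stopwords) &
    !(norm %in% config$stopwords)
  norm[keep]
}
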
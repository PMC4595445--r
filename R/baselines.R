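#' Bibliographic coupling similarity
#'
#' Jaccard overlap of the sets of works the two articles cite, compared by
#' resolved citation identity (references whose identity could not be
#' resolved are ignored).  When both sets are empty the similarity is 0.
#'
#' @param art1,art2 [article()]s.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
bc_similarity <- function(art1, art2) {
  o1 <- reference_identity_set(art1)
  o2 <- reference_identity_set(art2)
  u <- length(unique(c(o1, o2)))
  if (u == 0L) {
    return(0)
  }
  length(intersect(o1, o2)) / u
}

reference_identity_set <- function(art) {
  ids <- vapply(art$references, function(r) r$cited_article_id, character(1))
  unique(ids[!is.na(ids)])
}

#' BM25 parameters for the OK measure
#'
#' @param k1 term-frequency saturation, default 8.
#' @param b length-normalization strength in \code{[0, 1]}, default 1.0.
#' @return an object of class \code{bm25_params}.
#' @export
bm25_params <- function(k1 = 8, b = 1.0) {
  k1 <- as.numeric(k1)
  b <- as.numeric(b)
  if (is.na(k1) || k1 <= 0) stop("k1 must be positive")
  if (is.na(b) || b < 0 || b > 1) stop("b must lie in [0, 1]")
  structure(list(k1 = k1, b = b), class = "bm25_params")
}

article_field_tokens <- function(art, field_view) {
  if (field_view == "title_abstract") {
    sp <- art$abstract_span
    abs_toks <- if (sp[2] > sp[1]) {
      art$body_tokens[(sp[1] + 1L):sp[2]]
    } else {
      character(0)  # no abstract recorded: fall back to the title alone
    }
    c(art$title_tokens, abs_toks)
  } else {
    c(art$title_tokens, art$body_tokens)
  }
}

#' Collection statistics for the OK measure
#'
#' Term and document frequencies over the evaluation corpus under one field
#' view: \code{"title_abstract"} uses the title plus the abstract span of
#' each article, \code{"whole_article"} uses the title plus the full body.
#' The statistics (total article count, per-term document frequency, average
#' document length) feed the BM25-style scorer in [ok_similarity()].
#'
#' @param corp a [corpus()]; must be non-empty.
#' @param field_view \code{"title_abstract"} or \code{"whole_article"}.
#' @return an object of class \code{corpus_stats} with fields
#'   \code{field_view}, \code{N}, \code{doc_freq}, \code{avgdl},
#'   \code{term_freq} (per-article named count vectors), \code{doc_len}.
#' @export
build_corpus_stats <- function(corp,
                               field_view = c("title_abstract",
                                              "whole_article")) {
  stopifnot(inherits(corp, "pbc_corpus"))
  field_view <- match.arg(field_view)
  if (length(corp$articles) == 0L) {
    stop("cannot build corpus statistics from an empty corpus")
  }
  term_freq <- lapply(corp$articles, function(a) {
    toks <- article_field_tokens(a, field_view)
    if (length(toks) == 0L) {
      return(integer(0))
    }
    tab <- table(toks)
    stats::setNames(as.integer(tab), names(tab))
  })
  doc_len <- vapply(term_freq, sum, numeric(1))
  all_terms <- unlist(lapply(term_freq, names), use.names = FALSE)
  df_tab <- table(all_terms)
  structure(
    list(
      field_view = field_view,
      N = length(corp$articles),
      doc_freq = stats::setNames(as.integer(df_tab), names(df_tab)),
      avgdl = mean(doc_len),
      term_freq = term_freq,
      doc_len = doc_len
    ),
    class = "corpus_stats"
  )
}

#' BM25-based inter-article similarity (OK)
#'
#' Scores a pair of articles as the sum, over their shared terms, of the two
#' BM25 term-saturation factors times \code{log2(N / n)}, where \code{N} is
#' the collection size and \code{n} the number of articles containing the
#' term.  A shared term occurring in every article contributes nothing.  The
#' field view is fixed by the \code{corpus_stats} object, so the
#' title+abstract and whole-article versions share this code path.
#'
#' @param art1,art2 [article()]s present in \code{corpus_stats}.
#' @param corpus_stats a [build_corpus_stats()] result.
#' @param params a [bm25_params()].
#' @return non-negative numeric scalar.
#' @export
ok_similarity <- function(art1, art2, corpus_stats, params = bm25_params()) {
  stopifnot(inherits(corpus_stats, "corpus_stats"))
  tf1 <- corpus_stats$term_freq[[art1$article_id]]
  tf2 <- corpus_stats$term_freq[[art2$article_id]]
  if (is.null(tf1) || is.null(tf2)) {
    missing_id <- if (is.null(tf1)) art1$article_id else art2$article_id
    stop("article '", missing_id, "' is not in the corpus statistics")
  }
  shared <- intersect(names(tf1), names(tf2))
  if (length(shared) == 0L) {
    return(0)
  }
  k1 <- params$k1
  b <- params$b
  avgdl <- corpus_stats$avgdl
  sat <- function(tf, dl) {
    tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / avgdl))
  }
  n <- corpus_stats$doc_freq[shared]
  idf <- log2(corpus_stats$N / n)
  f1 <- sat(as.numeric(tf1[shared]), corpus_stats$doc_len[[art1$article_id]])
  f2 <- sat(as.numeric(tf2[shared]), corpus_stats$doc_len[[art2$article_id]])
  sum(f1 * f2 * idf)
}
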
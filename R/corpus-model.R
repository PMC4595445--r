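#' Article, section and reference constructors
#'
#' The corpus data model.  An article is a normalized token stream plus
#' structure on top of it: token indices are 0-based and all spans are
#' half-open \code{[start, end)}.  A reference's mention position is the index
#' of the first body token *after* the in-text citation marker, i.e. the
#' number of (stopword-removed) tokens preceding the marker; marker tokens
#' themselves are never part of the body stream.  A mention position may
#' therefore equal \code{length(body_tokens)} when a citation closes the
#' document.
#'
#' @param article_id opaque string identifier, unique within a corpus.
#' @param title_tokens ordered character vector of normalized title tokens.
#' @param body_tokens ordered character vector of normalized body tokens
#'   (stopwords removed), indexed from 0.
#' @param abstract_span length-2 integer vector, half-open token interval of
#'   the abstract inside \code{body_tokens} (may be empty).
#' @param sections list of [article_section()] objects, ordered and
#'   non-overlapping.
#' @param references list of [article_reference()] objects with unique
#'   \code{ref_id}s.
#' @return an object of class \code{pbc_article}.
#' @export
article <- function(article_id, title_tokens = character(0),
                    body_tokens = character(0),
                    abstract_span = c(0L, 0L),
                    sections = list(), references = list()) {
  art <- structure(
    list(
      article_id = as.character(article_id),
      title_tokens = as.character(title_tokens),
      body_tokens = as.character(body_tokens),
      abstract_span = as.integer(abstract_span),
      sections = sections,
      references = references
    ),
    class = "pbc_article"
  )
  validate_article(art)
  art
}

#' @rdname article
#' @param title_text raw section title string.
#' @param span length-2 integer vector, half-open token interval into the
#'   article's \code{body_tokens}.
#' @export
article_section <- function(title_text, span) {
  structure(
    list(title_text = as.character(title_text), span = as.integer(span)),
    class = "pbc_section"
  )
}

#' @rdname article
#' @param ref_id local reference key (e.g. the bibliography number or id).
#' @param cited_article_id resolved global identity of the cited work
#'   (\code{"pmid:..."}, \code{"doi:..."} or a normalized citation string);
#'   \code{NA} when unresolved.  Two references denote the same cited work iff
#'   both identities are resolved and equal.
#' @param mention_positions sorted integer vector of 0-based token positions
#'   where the citation marker occurs; may be empty (listed but never cited in
#'   the body).
#' @export
article_reference <- function(ref_id, cited_article_id = NA_character_,
                              mention_positions = integer(0)) {
  structure(
    list(
      ref_id = as.character(ref_id),
      cited_article_id = as.character(cited_article_id),
      mention_positions = as.integer(mention_positions)
    ),
    class = "pbc_reference"
  )
}

validate_article <- function(art) {
  id <- art$article_id
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("article_id must be a non-empty string")
  }
  n <- length(art$body_tokens)
  span_ok <- function(sp) {
    length(sp) == 2L && !anyNA(sp) && sp[1] >= 0L && sp[1] <= sp[2] &&
      sp[2] <= n
  }
  if (!span_ok(art$abstract_span)) {
    stop("invalid abstract_span in article '", id, "'")
  }
  prev_end <- 0L
  for (sec in art$sections) {
    if (!inherits(sec, "pbc_section") || !span_ok(sec$span)) {
      stop("invalid section span in article '", id, "'")
    }
    if (sec$span[1] < prev_end) {
      stop("overlapping or unordered sections in article '", id, "'")
    }
    prev_end <- sec$span[2]
  }
  ref_ids <- vapply(art$references, function(r) r$ref_id, character(1))
  if (anyDuplicated(ref_ids)) {
    stop("duplicate ref_id in article '", id, "'")
  }
  for (ref in art$references) {
    mp <- ref$mention_positions
    if (anyNA(mp) || any(mp < 0L) || any(mp > n)) {
      stop("mention position out of range [0, ", n, "] for reference '",
           ref$ref_id, "' in article '", id, "'")
    }
    if (is.unsorted(mp)) {
      stop("mention_positions not sorted for reference '", ref$ref_id,
           "' in article '", id, "'")
    }
  }
  invisible(art)
}

#' Build a corpus from articles
#'
#' @param articles list of [article()] objects; ids must be unique.
#' @return an object of class \code{pbc_corpus}: a named list of articles
#'   keyed by \code{article_id}.
#' @export
corpus <- function(articles = list()) {
  ids <- vapply(articles, function(a) a$article_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate article_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(articles) <- ids
  structure(list(articles = articles), class = "pbc_corpus")
}

#' @export
print.pbc_corpus <- function(x, ...) {
  cat("<pbc_corpus>", length(x$articles), "articles\n")
  invisible(x)
}

#' @export
print.pbc_article <- function(x, ...) {
  cat("<pbc_article>", x$article_id, "-", length(x$body_tokens),
      "body tokens,", length(x$references), "references\n")
  invisible(x)
}

corpus_article <- function(corp, article_id) {
  art <- corp$articles[[article_id]]
  if (is.null(art)) {
    stop("unknown article_id '", article_id, "'")
  }
  art
}

find_reference <- function(art, ref_id) {
  for (ref in art$references) {
    if (identical(ref$ref_id, as.character(ref_id))) {
      return(ref)
    }
  }
  stop("unknown ref_id '", ref_id, "' in article '", art$article_id, "'")
}

# -- JSON corpus dialect ------------------------------------------------------
#
# {"articles": {"<id>": {"article_id": "...", "title_tokens": [...],
#   "body_tokens": [...], "abstract_span": [a, b],
#   "sections": [{"title_text": "...", "span": [a, b]}, ...],
#   "references": [{"ref_id": "...", "cited_article_id": "..."|null,
#                   "mention_positions": [...]}, ...]}, ...}}

article_to_list <- function(art) {
  list(
    article_id = jsonlite::unbox(art$article_id),
    title_tokens = as.character(art$title_tokens),
    body_tokens = as.character(art$body_tokens),
    abstract_span = as.integer(art$abstract_span),
    sections = lapply(art$sections, function(s) {
      list(title_text = jsonlite::unbox(s$title_text),
           span = as.integer(s$span))
    }),
    references = lapply(art$references, function(r) {
      list(
        ref_id = jsonlite::unbox(r$ref_id),
        cited_article_id = if (is.na(r$cited_article_id)) NULL else
          jsonlite::unbox(r$cited_article_id),
        mention_positions = as.integer(r$mention_positions)
      )
    })
  )
}

#' Write / read a corpus in the JSON corpus dialect
#'
#' The dialect is a single JSON object \code{{"articles": {id: article}}}
#' whose article fields mirror [article()] exactly; reading a written corpus
#' reproduces it field-for-field.  Validation failures name the offending
#' field and article.
#'
#' @param corp a \code{pbc_corpus}.
#' @param path file path (UTF-8 JSON).
#' @return \code{read_corpus_json} returns a \code{pbc_corpus};
#'   \code{write_corpus_json} returns \code{path} invisibly.
#' @export
write_corpus_json <- function(corp, path) {
  stopifnot(inherits(corp, "pbc_corpus"))
  payload <- list(articles = lapply(corp$articles, article_to_list))
  if (length(payload$articles) == 0L) {
    payload$articles <- structure(list(), names = character(0))
  }
  json <- jsonlite::toJSON(payload, null = "null", digits = NA,
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_json
#' @export
read_corpus_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || is.null(raw$articles)) {
    stop("corpus JSON must contain an 'articles' object")
  }
  arts <- lapply(names(raw$articles), function(id) {
    a <- raw$articles[[id]]
    need <- c("article_id", "title_tokens", "body_tokens", "abstract_span",
              "sections", "references")
    missing <- setdiff(need, names(a))
    if (length(missing) > 0L) {
      stop("article '", id, "': missing field(s) ",
           paste(missing, collapse = ", "))
    }
    secs <- lapply(a$sections, function(s) {
      article_section(s$title_text, unlist(s$span))
    })
    refs <- lapply(a$references, function(r) {
      article_reference(
        ref_id = r$ref_id,
        cited_article_id = if (is.null(r$cited_article_id))
          NA_character_ else r$cited_article_id,
        mention_positions = as.integer(unlist(r$mention_positions))
      )
    })
    tryCatch(
      article(
        article_id = a$article_id,
        title_tokens = as.character(unlist(a$title_tokens)),
        body_tokens = as.character(unlist(a$body_tokens)),
        abstract_span = as.integer(unlist(a$abstract_span)),
        sections = secs,
        references = refs
      ),
      error = function(e) {
        stop("invalid article '", id, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  corpus(arts)
}

# -- qrels --------------------------------------------------------------------

#' Relevance judgments (qrels)
#'
#' One topic per retrieval task: a target article, its candidate pool, and
#' the expert-labelled highly related candidates.  Serialized as tab-separated
#' text with columns \code{topic_id}, \code{target_id}, \code{candidate_id},
#' \code{label} (1 = highly related, 0 = not).
#'
#' @param topics list; each element has fields \code{topic_id},
#'   \code{target_id}, \code{candidate_ids}, \code{highly_related_ids}.
#' @return an object of class \code{pbc_qrels}.
#' @export
qrels <- function(topics) {
  for (tp in topics) {
    if (!all(tp$highly_related_ids %in% tp$candidate_ids)) {
      stop("topic '", tp$topic_id,
           "': highly related ids must be a subset of the candidates")
    }
    if (tp$target_id %in% tp$candidate_ids) {
      stop("topic '", tp$topic_id, "': target must not be a candidate")
    }
    if (length(tp$highly_related_ids) < 1L) {
      stop("topic '", tp$topic_id, "': needs >= 1 highly related candidate")
    }
  }
  ids <- vapply(topics, function(tp) tp$topic_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate topic_id in qrels")
  }
  names(topics) <- ids
  structure(list(topics = topics), class = "pbc_qrels")
}

#' @rdname qrels
#' @param path tab-separated qrels file.
#' @export
read_qrels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("topic_id", "target_id", "candidate_id", "label")
  if (!all(need %in% names(df))) {
    stop("qrels file must have columns: ", paste(need, collapse = ", "))
  }
  topics <- lapply(split(df, df$topic_id), function(d) {
    list(
      topic_id = d$topic_id[1],
      target_id = d$target_id[1],
      candidate_ids = d$candidate_id,
      highly_related_ids = d$candidate_id[d$label == "1"]
    )
  })
  qrels(unname(topics[unique(df$topic_id)]))
}

#' @rdname qrels
#' @param qr a \code{pbc_qrels}.
#' @export
write_qrels <- function(qr, path) {
  stopifnot(inherits(qr, "pbc_qrels"))
  rows <- do.call(rbind, lapply(qr$topics, function(tp) {
    data.frame(
      topic_id = tp$topic_id,
      target_id = tp$target_id,
      candidate_id = tp$candidate_ids,
      label = as.integer(tp$candidate_ids %in% tp$highly_related_ids),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
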
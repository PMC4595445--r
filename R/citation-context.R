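#' Context passage of a reference
#'
#' The context passage of reference \code{c} in article \code{d} is the set
#' union of the article's title tokens with, for every place where \code{c}
#' is cited, the \code{alpha} body tokens immediately before that place.
#' The window is counted on the stopword-removed token stream, may cross
#' sentence and section boundaries, and is truncated at the document start.
#' A reference never cited in the body gets a title-only passage.
#'
#' @param art an [article()].
#' @param ref_id reference key inside \code{art}.
#' @param alpha positive integer window size; around 10 works well because a
#'   citation is typically commented in about one sentence.
#' @return character vector: the passage token *set* (unique, unordered).
#' @export
extract_context_passage <- function(art, ref_id, alpha = 10L) {
  alpha <- as.integer(alpha)
  if (is.na(alpha) || alpha < 1L) {
    stop("alpha must be a positive integer")
  }
  ref <- find_reference(art, ref_id)
  toks <- art$title_tokens
  for (p in ref$mention_positions) {
    # p is 0-based: tokens strictly before position p are at R indices 1..p
    lo <- max(1L, p - alpha + 1L)
    if (p >= 1L) {
      toks <- c(toks, art$body_tokens[lo:p])
    }
  }
  unique(toks)
}

#' Citation importance strategies
#'
#' Weight each reference by how central it is to the citing article.
#' \describe{
#'   \item{\code{importance_freq}}{2 if the reference is cited at least twice
#'     in the body, else 1.  References discussed repeatedly tend to be
#'     compared or built upon rather than background.}
#'   \item{\code{importance_pos}}{\code{1 + max(p) / Length(d)} over mention
#'     ordinals \code{p}, where \code{Length(d)} is the body token count and a
#'     mention's ordinal is the number of tokens at or before it; a citation
#'     after the final token scores exactly 2.  Returns 1 with no mentions.}
#'   \item{\code{importance_section}}{2 if any mention falls in or after the
#'     first section whose title contains "result" (case-insensitive), else 1;
#'     1 when the article has no such section.}
#' }
#'
#' @param art an [article()].
#' @param ref_id reference key inside \code{art}.
#' @return \code{importance_freq}, \code{importance_section}: 1 or 2;
#'   \code{importance_pos}: a value in \code{[1, 2]}.
#' @export
importance_freq <- function(art, ref_id) {
  ref <- find_reference(art, ref_id)
  if (length(ref$mention_positions) >= 2L) 2 else 1
}

#' @rdname importance_freq
#' @export
importance_pos <- function(art, ref_id) {
  ref <- find_reference(art, ref_id)
  mp <- ref$mention_positions
  if (length(mp) == 0L) {
    return(1)
  }
  len <- length(art$body_tokens)
  if (len == 0L) {
    stop("article '", art$article_id,
         "' has an empty body but a mentioned reference")
  }
  1 + max(mp) / len
}

#' @rdname importance_freq
#' @export
importance_section <- function(art, ref_id) {
  ref <- find_reference(art, ref_id)
  start <- result_section_start(art)
  if (is.na(start)) {
    return(1)
  }
  if (any(ref$mention_positions >= start)) 2 else 1
}

result_section_start <- function(art) {
  for (sec in art$sections) {
    if (grepl("result", sec$title_text, ignore.case = TRUE)) {
      return(sec$span[1])
    }
  }
  NA_integer_
}

importance_fun <- function(strategy = c("frequency", "position", "section")) {
  switch(match.arg(strategy),
         frequency = importance_freq,
         position = importance_pos,
         section = importance_section)
}
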
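#' Read one JATS/NXML full-text article
#'
#' Parses a PMC-style JATS document into the corpus data model.  In-text
#' citations are recognized from typed cross-reference elements
#' (\code{<xref ref-type="bibr" rid="...">}); the marker text itself (the
#' bibliography number) is excluded from the body token stream, and each
#' marker is recorded as a mention at the index of the first body token after
#' the text that precedes it.  Grouped citations (\code{[3,4]} as adjacent
#' cross-references) therefore share one mention position.  Only
#' body-paragraph markers count as mentions: tables, figures and their
#' captions are skipped.
#'
#' The cited work's identity is resolved from the bibliography entry in this
#' order: PMID if present, then DOI, then a lowercased alphanumeric
#' normalization of the citation text; unresolvable entries get \code{NA}.
#'
#' @param xml_document path to an NXML file, a literal XML string, or an
#'   \code{xml2} document.
#' @param config a [preprocessing_config()] applied to the title, abstract and
#'   body text.
#' @return an [article()].
#' @export
read_jats_article <- function(xml_document, config = preprocessing_config()) {
  doc <- tryCatch(
    if (inherits(xml_document, "xml_document")) xml_document else
      xml2::read_xml(xml_document),
    error = function(e) {
      stop("JATS parse error: ", conditionMessage(e), call. = FALSE)
    }
  )

  title_node <- xml2::xml_find_first(doc, ".//front//article-title")
  if (inherits(title_node, "xml_missing")) {
    title_node <- xml2::xml_find_first(doc, ".//article-title")
  }
  if (inherits(title_node, "xml_missing")) {
    stop("JATS validation error: missing article-title")
  }
  title_tokens <- preprocess_text(xml2::xml_text(title_node), config)

  art_id <- jats_article_id(doc)

  # token accumulator shared by the walkers
  st <- new.env(parent = emptyenv())
  st$tokens <- list()
  st$count <- 0L
  st$mentions <- list()  # ref_id -> integer positions

  emit_text <- function(txt) {
    toks <- preprocess_text(txt, config)
    if (length(toks) > 0L) {
      st$tokens[[length(st$tokens) + 1L]] <- toks
      st$count <- st$count + length(toks)
    }
  }
  record_mention <- function(rid) {
    for (id in strsplit(rid, "[[:space:]]+")[[1]]) {
      if (!nzchar(id)) next
      st$mentions[[id]] <- c(st$mentions[[id]], st$count)
    }
  }
  skip_elems <- c("table-wrap", "fig", "fig-group", "caption", "graphic",
                  "media", "disp-formula", "ref-list", "title",
                  "table-wrap-group", "supplementary-material")
  walk <- function(node) {
    for (child in xml2::xml_contents(node)) {
      nm <- xml2::xml_name(child)
      if (nm == "text" || nm == "cdata") {
        emit_text(xml2::xml_text(child))
      } else if (nm == "xref") {
        if (identical(xml2::xml_attr(child, "ref-type"), "bibr")) {
          rid <- xml2::xml_attr(child, "rid")
          if (!is.na(rid)) record_mention(rid)
        }
        # non-bibliography xrefs (figures, tables): marker text dropped
      } else if (!(nm %in% skip_elems)) {
        walk(child)
      }
    }
  }

  abstract_node <- xml2::xml_find_first(doc, ".//front//abstract")
  if (!inherits(abstract_node, "xml_missing")) {
    walk(abstract_node)
  }
  abstract_span <- c(0L, st$count)

  sections <- list()
  body_node <- xml2::xml_find_first(doc, ".//body")
  if (!inherits(body_node, "xml_missing")) {
    for (child in xml2::xml_contents(body_node)) {
      nm <- xml2::xml_name(child)
      if (nm == "sec") {
        sec_title <- xml2::xml_find_first(child, "./title")
        sec_title <- if (inherits(sec_title, "xml_missing")) "" else
          xml2::xml_text(sec_title)
        start <- st$count
        walk(child)
        sections[[length(sections) + 1L]] <-
          article_section(sec_title, c(start, st$count))
      } else if (nm == "text" || nm == "cdata") {
        emit_text(xml2::xml_text(child))
      } else if (!(nm %in% skip_elems)) {
        walk(child)
      }
    }
  }

  refs <- jats_references(doc, st$mentions)

  article(
    article_id = art_id,
    title_tokens = title_tokens,
    body_tokens = unlist(st$tokens, use.names = FALSE),
    abstract_span = abstract_span,
    sections = sections,
    references = refs
  )
}

jats_article_id <- function(doc) {
  for (typ in c("pmc", "pmcid", "pmid", "doi", "publisher-id")) {
    node <- xml2::xml_find_first(
      doc, paste0(".//front//article-id[@pub-id-type='", typ, "']"))
    if (!inherits(node, "xml_missing")) {
      return(xml2::xml_text(node))
    }
  }
  node <- xml2::xml_find_first(doc, ".//front//article-id")
  if (!inherits(node, "xml_missing")) {
    return(xml2::xml_text(node))
  }
  "unidentified-article"
}

jats_references <- function(doc, mentions) {
  ref_nodes <- xml2::xml_find_all(doc, ".//back//ref-list/ref")
  if (length(ref_nodes) == 0L) {
    ref_nodes <- xml2::xml_find_all(doc, ".//ref-list/ref")
  }
  refs <- vector("list", length(ref_nodes))
  for (i in seq_along(ref_nodes)) {
    node <- ref_nodes[[i]]
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) rid <- paste0("ref-", i)
    refs[[i]] <- article_reference(
      ref_id = rid,
      cited_article_id = jats_citation_identity(node),
      mention_positions = sort(unique(as.integer(mentions[[rid]])))
    )
  }
  refs
}

#' @keywords internal
jats_citation_identity <- function(ref_node) {
  pmid <- xml2::xml_find_first(ref_node, ".//pub-id[@pub-id-type='pmid']")
  if (!inherits(pmid, "xml_missing")) {
    return(paste0("pmid:", trimws(xml2::xml_text(pmid))))
  }
  doi <- xml2::xml_find_first(ref_node, ".//pub-id[@pub-id-type='doi']")
  if (!inherits(doi, "xml_missing")) {
    return(paste0("doi:", tolower(trimws(xml2::xml_text(doi)))))
  }
  normalize_citation_string(xml2::xml_text(ref_node))
}

#' Normalize a free-text citation into a comparable identity
#'
#' Fallback identity for bibliography entries without a PMID or DOI:
#' lowercase, keep alphanumerics only.  Returns \code{NA} for empty input.
#' @param x citation string.
#' @keywords internal
normalize_citation_string <- function(x) {
  key <- gsub("[^[:alnum:]]+", "", tolower(x))
  if (!nzchar(key)) {
    return(NA_character_)
  }
  paste0("str:", key)
}
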
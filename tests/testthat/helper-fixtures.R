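# Hand-built fixtures shared across test files.

# title {epo, anemia}; body of 5 tokens; one reference mentioned at 0-based
# position 3 (i.e. after "treatment")
epo_article <- function() {
  article(
    "epo1",
    title_tokens = c("epo", "anemia"),
    body_tokens = c("anemia", "erythropoietin", "treatment", "improve",
                    "outcome"),
    abstract_span = c(0L, 0L),
    references = list(article_reference("c1", "pmid:100", 3L))
  )
}

# 12-token body with one reference mentioned twice, for multi-window checks
two_mention_article <- function() {
  article(
    "tm1",
    title_tokens = c("title1", "title2"),
    body_tokens = c("w01", "w02", "w03", "w04", "w05", "w06",
                    "w07", "w08", "w09", "w10", "w11", "w12"),
    references = list(
      article_reference("c1", "pmid:200", c(3L, 10L)),
      article_reference("c2", "pmid:201", integer(0))
    )
  )
}

# build a minimal article around explicit reference specs:
# refs = list(list(id=, ident=, mentions=))
mini_article <- function(article_id, refs, body_len = 20L,
                         title = c("alpha", "beta"), sections = list()) {
  article(
    article_id,
    title_tokens = title,
    body_tokens = sprintf("%s-b%02d", article_id, seq_len(body_len)),
    sections = sections,
    references = lapply(refs, function(r) {
      article_reference(r$id, r$ident, as.integer(r$mentions))
    })
  )
}

minimal_nxml <- function() {
  paste0(
    "<article>",
    "<front><article-meta>",
    "<article-id pub-id-type=\"pmc\">PMC1</article-id>",
    "<title-group><article-title>EPO in anemia</article-title>",
    "</title-group>",
    "<abstract><p>Erythropoietin helps anemia patients</p></abstract>",
    "</article-meta></front>",
    "<body><sec><title>Introduction</title>",
    "<p>Erythropoietin treatment improves outcomes ",
    "<xref ref-type=\"bibr\" rid=\"B1\">1</xref> in anemia.</p>",
    "</sec></body>",
    "<back><ref-list>",
    "<ref id=\"B1\"><mixed-citation>Smith J. EPO study. 2001.",
    "</mixed-citation></ref>",
    "</ref-list></back>",
    "</article>"
  )
}

uncited_refs_nxml <- function() {
  paste0(
    "<article>",
    "<front><article-meta>",
    "<title-group><article-title>Uncited bibliography</article-title>",
    "</title-group></article-meta></front>",
    "<body><sec><title>Main</title><p>Plain body text here</p></sec></body>",
    "<back><ref-list>",
    "<ref id=\"B1\"><mixed-citation>First work</mixed-citation></ref>",
    "<ref id=\"B2\"><mixed-citation>Second work</mixed-citation></ref>",
    "<ref id=\"B3\"><mixed-citation>Third work</mixed-citation></ref>",
    "</ref-list></back>",
    "</article>"
  )
}

grouped_citation_nxml <- function() {
  paste0(
    "<article>",
    "<front><article-meta>",
    "<title-group><article-title>Grouped citations</article-title>",
    "</title-group></article-meta></front>",
    "<body><sec><title>Results</title>",
    "<p>Receptor signalling pathway [",
    "<xref ref-type=\"bibr\" rid=\"B1\">1</xref>,",
    "<xref ref-type=\"bibr\" rid=\"B2\">2</xref>] confirmed findings.</p>",
    "</sec></body>",
    "<back><ref-list>",
    "<ref id=\"B1\"><pub-id pub-id-type=\"pmid\">11</pub-id></ref>",
    "<ref id=\"B2\"><pub-id pub-id-type=\"doi\">10.1/x</pub-id></ref>",
    "</ref-list></back>",
    "</article>"
  )
}
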
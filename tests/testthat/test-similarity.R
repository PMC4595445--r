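test_that("reference-pair similarity: identity match, passage Jaccard, and
           the empty-passage convention", {
  # identical resolved identities score 1 regardless of passages
  a1 <- mini_article("a1", list(list(id = "r1", ident = "pmid:7",
                                     mentions = 5)))
  a2 <- mini_article("a2", list(list(id = "r1", ident = "pmid:7",
                                     mentions = 12)))
  expect_equal(link_sim(a1, "r1", a2, "r1"), 1)

  # CP1 = {a,b,c}, CP2 = {b,c,d} -> 2/4 (titles give a/b vs c/d overlap
  # pattern built explicitly from token streams)
  b1 <- article("b1", c("a"), c("b", "c"),
                references = list(article_reference("r", "x1", 2L)))
  b2 <- article("b2", c("d"), c("b", "c"),
                references = list(article_reference("r", "x2", 2L)))
  expect_equal(link_sim(b1, "r", b2, "r", alpha = 2), 0.5)

  # disjoint passages, different identities
  c1 <- mini_article("c1", list(list(id = "r", ident = "x1", mentions = 5)),
                     title = c("t1", "t2"))
  c2 <- mini_article("c2", list(list(id = "r", ident = "x2", mentions = 5)),
                     title = c("u1", "u2"))
  expect_equal(link_sim(c1, "r", c2, "r"), 0)

  # both passages empty (no title, no mentions), different identities -> 0
  e1 <- article("e1", character(0), "w",
                references = list(article_reference("r", "x1")))
  e2 <- article("e2", character(0), "w",
                references = list(article_reference("r", "x2")))
  expect_equal(link_sim(e1, "r", e2, "r"), 0)

  # unresolved identities never count as equal
  u1 <- article("u1", "t", "w",
                references = list(article_reference("r", NA)))
  u2 <- article("u2", "t", "w",
                references = list(article_reference("r", NA)))
  expect_equal(link_sim(u1, "r", u2, "r"),
               1)  # via the text branch: identical title-only passages
  expect_equal(link_sim(u1, "r", u2, "r",
                        variant = pbc_variant(link_component = TRUE,
                                              text_component = FALSE)),
               0)
})

test_that("ablation variants use only their branch of the pair score", {
  a1 <- mini_article("a1", list(list(id = "r", ident = "pmid:7",
                                     mentions = 5)), title = c("x", "y"))
  a2 <- mini_article("a2", list(list(id = "r", ident = "pmid:7",
                                     mentions = 5)), title = c("x", "z"))
  link_only <- pbc_variant("frequency", TRUE, FALSE)
  text_only <- pbc_variant("frequency", FALSE, TRUE)
  expect_equal(link_sim(a1, "r", a2, "r", variant = link_only), 1)
  # text-only scores the Jaccard even for identical citations
  jac <- link_sim(a1, "r", a2, "r", variant = text_only)
  expect_lt(jac, 1)
  expect_gt(jac, 0)
  expect_error(pbc_variant(link_component = FALSE, text_component = FALSE),
               "at least one")
})

test_that("importance-weighted pair similarity multiplies by mean IMP", {
  # link_sim = 1 (same identity), IMP 2 and 1
  a1 <- mini_article("a1", list(list(id = "r", ident = "pmid:7",
                                     mentions = c(3, 9))))
  a2 <- mini_article("a2", list(list(id = "r", ident = "pmid:7",
                                     mentions = 5)))
  expect_equal(link_sim_imp(a1, "r", a2, "r"), 1.5)
  # link_sim = 0 -> 0 regardless of importance
  z1 <- mini_article("z1", list(list(id = "r", ident = "x1",
                                     mentions = c(3, 9))),
                     title = c("t1", "t2"))
  z2 <- mini_article("z2", list(list(id = "r", ident = "x2",
                                     mentions = c(3, 9))),
                     title = c("u1", "u2"))
  expect_equal(link_sim_imp(z1, "r", z2, "r"), 0)
  # half-overlap passages with both references important: 0.5 * 2 = 1
  h1 <- article("h1", c("a"), c("b", "c"),
                references = list(article_reference("r", "x1", c(2L, 2L))))
  h2 <- article("h2", c("d"), c("b", "c"),
                references = list(article_reference("r", "x2", c(2L, 2L))))
  expect_equal(link_sim_imp(h1, "r", h2, "r", alpha = 2), 1)
})

test_that("article-level score: worked endpoints of the aggregation", {
  # self-similarity with every reference mentioned exactly once -> 1
  a <- mini_article("a", list(list(id = "r1", ident = "p:1", mentions = 4),
                              list(id = "r2", ident = "p:2", mentions = 9)))
  expect_equal(pbc_similarity(a, a), 1)
  # one common work cited >= 2 times in each article -> 2
  m1 <- mini_article("m1", list(list(id = "r", ident = "p:9",
                                     mentions = c(3, 8))))
  m2 <- mini_article("m2", list(list(id = "r", ident = "p:9",
                                     mentions = c(2, 11))))
  expect_equal(pbc_similarity(m1, m2), 2)
  # disjoint references and disjoint passages -> 0
  d1 <- mini_article("d1", list(list(id = "r", ident = "x1", mentions = 5)),
                     title = c("t1", "t2"))
  d2 <- mini_article("d2", list(list(id = "r", ident = "x2", mentions = 5)),
                     title = c("u1", "u2"))
  expect_equal(pbc_similarity(d1, d2), 0)
  # empty reference list on either side -> 0
  none <- article("none", "t", c("w1", "w2"))
  expect_equal(pbc_similarity(none, a), 0)
  expect_equal(pbc_similarity(a, none), 0)
})

test_that("article score is symmetric, bounded, and equal to brute-force
           pair enumeration on random corpora", {
  set.seed(21)
  vocab <- sprintf("v%02d", 1:20)
  pool <- sprintf("shared%02d", 1:6)
  for (trial in 1:40) {
    a1 <- random_article(paste0("x", trial), vocab,
                         shared_identity_pool = pool)
    a2 <- random_article(paste0("y", trial), vocab,
                         shared_identity_pool = pool)
    for (variant in list(pbc_variant("frequency"),
                         pbc_variant("position"),
                         pbc_variant("section"),
                         pbc_variant("frequency", TRUE, FALSE),
                         pbc_variant("frequency", FALSE, TRUE))) {
      s12 <- pbc_similarity(a1, a2, alpha = 3, variant = variant)
      s21 <- pbc_similarity(a2, a1, alpha = 3, variant = variant)
      expect_equal(s12, s21)
      expect_gte(s12, 0)
      expect_lte(s12, 2)
      expect_equal(
        s12,
        oracle_pbc(a1, a2, alpha = 3,
                   strategy = variant$importance_strategy,
                   link = variant$link_component,
                   text = variant$text_component))
    }
  }
})

test_that("link-only scoring with uniform importance reduces to the Dice
           coefficient of the reference-identity sets", {
  set.seed(31)
  ident_pool <- sprintf("p:%02d", 1:12)
  link_only <- pbc_variant("frequency", TRUE, FALSE)
  for (trial in 1:25) {
    ids1 <- sample(ident_pool, sample(1:6, 1))
    ids2 <- sample(ident_pool, sample(1:6, 1))
    # at most one mention per reference keeps every IMP at 1
    mk <- function(aid, ids) {
      mini_article(aid, lapply(seq_along(ids), function(k) {
        list(id = paste0("r", k), ident = ids[k], mentions = k)
      }), body_len = length(ids) + 2)
    }
    a1 <- mk("a1", ids1)
    a2 <- mk("a2", ids2)
    dice <- 2 * length(intersect(ids1, ids2)) /
      (length(ids1) + length(ids2))
    expect_equal(pbc_similarity(a1, a2, variant = link_only), dice)
  }
})

test_that("adding a token shared by both passages never decreases the text
           term", {
  set.seed(41)
  for (trial in 1:20) {
    i <- sample(0:8, 1)          # shared tokens
    u <- i + sample(1:8, 1)      # union size
    expect_gte((i + 1) / (u + 1), i / max(u, 1))
  }
  # concrete check through the token streams
  b1 <- article("b1", c("s1"), c("p", "q"),
                references = list(article_reference("r", "x1", 2L)))
  b2 <- article("b2", c("s2"), c("p", "q"),
                references = list(article_reference("r", "x2", 2L)))
  base <- link_sim(b1, "r", b2, "r", alpha = 1)   # windows {q}
  more <- link_sim(b1, "r", b2, "r", alpha = 2)   # windows {p, q}
  expect_gte(more, base)
})

test_that("pairwise score caching returns identical values on repeat
           queries", {
  gen <- generate_corpus(synth_config(n_topics = 2, n_near_miss = 3,
                                      seed = 5))
  arts <- gen$corpus$articles
  cache <- similarity_cache()
  s1 <- pbc_similarity(arts[[1]], arts[[2]], cache = cache)
  s2 <- pbc_similarity(arts[[1]], arts[[2]], cache = cache)
  s_rev <- pbc_similarity(arts[[2]], arts[[1]], cache = cache)
  s_plain <- pbc_similarity(arts[[1]], arts[[2]])
  expect_identical(s1, s2)
  expect_identical(s1, s_rev)
  expect_equal(s1, s_plain)
})

test_that("candidate ranking sorts by descending score with ascending-id
           ties", {
  t1 <- mini_article("t1", list(list(id = "r", ident = "p:1", mentions = 3)))
  same_b <- mini_article("b-cand",
                         list(list(id = "r", ident = "p:1", mentions = 3)))
  same_a <- mini_article("a-cand",
                         list(list(id = "r", ident = "p:1", mentions = 3)))
  diff <- mini_article("z-cand",
                       list(list(id = "r", ident = "p:9", mentions = 3)),
                       title = c("q1", "q2"))
  rr <- rank_candidates(t1, list(same_b, diff, same_a), measure = "PBC",
                        topic_id = "t")
  expect_identical(rr$ranking$candidate_id, c("a-cand", "b-cand", "z-cand"))
  expect_identical(rr$ranking$rank, 1:3)
  single <- rank_candidates(t1, list(diff), measure = "BC")
  expect_identical(single$ranking$rank, 1L)
  empty <- rank_candidates(t1, list(), measure = "PBC")
  expect_identical(nrow(empty$ranking), 0L)
  expect_error(rank_candidates(t1, list(diff), measure = "nope"),
               "unknown measure")
})

test_that("run files round-trip rankings exactly", {
  gen <- generate_corpus(synth_config(n_topics = 2, n_near_miss = 4,
                                      seed = 9))
  runs <- rank_all_topics(gen$corpus, gen$qrels, measures = c("PBC", "BC"))
  flat <- unlist(unname(runs), recursive = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_run_file(flat, path)
  back <- read_run_file(path)
  expect_length(back, length(flat))
  got <- back[[1]]
  want <- flat[[1]]
  expect_identical(got$topic_id, want$topic_id)
  expect_identical(got$ranking$candidate_id, want$ranking$candidate_id)
  expect_equal(got$ranking$score, want$ranking$score)
})
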
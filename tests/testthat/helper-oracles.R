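# Independent brute-force oracles.  These re-derive every quantity from the
# raw token streams with naive loops and never call the package's similarity
# or evaluation code paths.

oracle_cp <- function(art, ref_id, alpha) {
  ref <- NULL
  for (r in art$references) if (r$ref_id == ref_id) ref <- r
  out <- art$title_tokens
  for (p in ref$mention_positions) {
    for (k in seq_len(alpha)) {
      idx <- p - k           # 0-based index of a token before the mention
      if (idx >= 0) out <- c(out, art$body_tokens[idx + 1])
    }
  }
  unique(out)
}

oracle_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  sum(u %in% a & u %in% b) / length(u)
}

oracle_imp <- function(art, ref_id, strategy) {
  ref <- NULL
  for (r in art$references) if (r$ref_id == ref_id) ref <- r
  mp <- ref$mention_positions
  if (strategy == "frequency") {
    if (length(mp) >= 2) 2 else 1
  } else if (strategy == "position") {
    if (length(mp) == 0) 1 else 1 + max(mp) / length(art$body_tokens)
  } else {
    start <- NA
    for (s in art$sections) {
      if (grepl("result", s$title_text, ignore.case = TRUE)) {
        start <- s$span[1]
        break
      }
    }
    if (!is.na(start) && length(mp) > 0 && any(mp >= start)) 2 else 1
  }
}

oracle_link_sim <- function(art1, rid1, art2, rid2, alpha,
                            link = TRUE, text = TRUE) {
  id1 <- id2 <- NA
  for (r in art1$references) if (r$ref_id == rid1) id1 <- r$cited_article_id
  for (r in art2$references) if (r$ref_id == rid2) id2 <- r$cited_article_id
  same <- !is.na(id1) && !is.na(id2) && id1 == id2
  jac <- oracle_jaccard(oracle_cp(art1, rid1, alpha),
                        oracle_cp(art2, rid2, alpha))
  if (link && text) {
    if (same) 1 else jac
  } else if (link) {
    as.numeric(same)
  } else {
    jac
  }
}

# full enumeration of every (c1, c2) reference pair
oracle_pbc <- function(art1, art2, alpha, strategy = "frequency",
                       link = TRUE, text = TRUE) {
  r1 <- vapply(art1$references, function(r) r$ref_id, character(1))
  r2 <- vapply(art2$references, function(r) r$ref_id, character(1))
  if (length(r1) == 0 || length(r2) == 0) return(0)
  lsi <- function(a, b) {
    oracle_link_sim(art1, a, art2, b, alpha, link, text) *
      (oracle_imp(art1, a, strategy) + oracle_imp(art2, b, strategy)) / 2
  }
  s <- 0
  for (a in r1) s <- s + max(vapply(r2, function(b) lsi(a, b), numeric(1)))
  for (b in r2) s <- s + max(vapply(r1, function(a) lsi(a, b), numeric(1)))
  s / (length(r1) + length(r2))
}

oracle_ap <- function(ranked_ids, relevant_ids) {
  hits <- 0
  s <- 0
  for (i in seq_along(ranked_ids)) {
    if (ranked_ids[i] %in% relevant_ids) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / length(relevant_ids)
}

# small random articles for property tests; independent of the package's
# synthetic-corpus module
random_article <- function(id, vocab, max_refs = 5, max_body = 30,
                           shared_identity_pool = character(0)) {
  n_body <- sample.int(max_body, 1)
  body <- sample(vocab, n_body, replace = TRUE)
  n_refs <- sample.int(max_refs, 1)
  refs <- lapply(seq_len(n_refs), function(k) {
    ident <- if (length(shared_identity_pool) > 0 && stats::runif(1) < 0.5) {
      sample(shared_identity_pool, 1)
    } else {
      paste0("uniq-", id, "-", k)
    }
    n_m <- sample(0:3, 1)
    article_reference(paste0("r", k), ident,
                      sort(sample(0:n_body, min(n_m, n_body + 1))))
  })
  secs <- if (n_body >= 2 && stats::runif(1) < 0.5) {
    mid <- sample.int(n_body - 1, 1)
    list(article_section("Methods", c(0L, mid)),
         article_section("Results", c(mid, n_body)))
  } else {
    list()
  }
  article(id, sample(vocab, sample.int(4, 1)), body,
          c(0L, min(5L, n_body)), secs, refs)
}
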
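#' Synthetic citation-corpus configuration
#'
#' Describes a corpus with planted related-article structure: articles are
#' grouped into topic clusters (one target plus its highly related
#' candidates, emulating the expert-selected articles of one gene-disease
#' pair), padded with "near-miss" candidates that share only part of the
#' topic vocabulary (emulating articles that mention the gene or the disease
#' but not both).  Cluster vocabularies are disjoint token blocks plus a
#' shared common block, so overlap levels are enforced by construction and
#' expected similarity values are analyzable.  Generation is a pure function
#' of (config, seed).
#'
#' @param n_topics number of topic clusters (default 20).
#' @param cluster_size articles per cluster including the target, so
#'   \code{cluster_size - 1} highly related candidates per topic (default 4,
#'   i.e. 3 highly related candidates, close to the 2-3 expert-selected
#'   articles typically available per gene-disease pair).
#' @param n_near_miss near-miss candidates per topic (default 30; a
#'   desk-scale stand-in for the ~200 retrieved per pair in a full corpus).
#' @param vocab_size cluster-specific content vocabulary size; split into two
#'   halves playing the roles of "gene words" and "disease words" (default
#'   40, must be even).
#' @param shared_vocab_size size of the common vocabulary available to every
#'   article (default 20).
#' @param reference_pool_size identities in each cluster's reference pool
#'   (default 30; must be >= \code{n_refs_per_article}).
#' @param n_refs_per_article references per article (default 10).
#' @param p_shared_reference probability that a reference of a cluster member
#'   is drawn from the cluster pool (and can therefore coincide with another
#'   member's reference) rather than being globally unique (default 0.5).
#' @param passage_overlap probability that a context-window token of a
#'   cluster member comes from the cluster vocabulary rather than from an
#'   article-private filler block (default 0.6); near-miss articles draw
#'   their in-vocabulary tokens from one half of the cluster vocabulary only.
#' @param mention_count_probs probabilities of a reference being mentioned
#'   1, 2, ... times (default \code{c(0.6, 0.4)}).
#' @param window_len tokens written immediately before each mention; sized to
#'   the context window of the similarity measure (default 10).
#' @param title_len title tokens per article (default 6).
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(n_topics = 20L, cluster_size = 4L,
                         n_near_miss = 30L, vocab_size = 40L,
                         shared_vocab_size = 20L,
                         reference_pool_size = 30L,
                         n_refs_per_article = 10L,
                         p_shared_reference = 0.5,
                         passage_overlap = 0.6,
                         mention_count_probs = c(0.6, 0.4),
                         window_len = 10L, title_len = 6L, seed = 1L) {
  cfg <- list(
    n_topics = as.integer(n_topics),
    cluster_size = as.integer(cluster_size),
    n_near_miss = as.integer(n_near_miss),
    vocab_size = as.integer(vocab_size),
    shared_vocab_size = as.integer(shared_vocab_size),
    reference_pool_size = as.integer(reference_pool_size),
    n_refs_per_article = as.integer(n_refs_per_article),
    p_shared_reference = as.numeric(p_shared_reference),
    passage_overlap = as.numeric(passage_overlap),
    mention_count_probs = as.numeric(mention_count_probs),
    window_len = as.integer(window_len),
    title_len = as.integer(title_len),
    seed = as.integer(seed)
  )
  sizes <- c("n_topics", "cluster_size", "n_near_miss", "vocab_size",
             "shared_vocab_size", "reference_pool_size",
             "n_refs_per_article", "window_len", "title_len")
  for (f in sizes) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("config error: ", f, " must be >= 1")
    }
  }
  if (cfg$cluster_size < 2L) {
    stop("config error: cluster_size must be >= 2 (target plus >= 1 ",
         "highly related candidate)")
  }
  if (cfg$vocab_size %% 2L != 0L) {
    stop("config error: vocab_size must be even")
  }
  for (f in c("p_shared_reference", "passage_overlap")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config error: ", f, " must lie in [0, 1]")
    }
  }
  if (any(cfg$mention_count_probs < 0) ||
      abs(sum(cfg$mention_count_probs) - 1) > 1e-8) {
    stop("config error: mention_count_probs must be a probability vector")
  }
  if (cfg$reference_pool_size < cfg$n_refs_per_article) {
    stop("config error: reference pool (", cfg$reference_pool_size,
         ") smaller than references per article (",
         cfg$n_refs_per_article, ")")
  }
  structure(cfg, class = "synth_config")
}

# run code under a given seed without leaking RNG state to the caller
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic corpus with planted related-article structure
#'
#' For each topic: one target article, \code{cluster_size - 1} highly related
#' candidates drawing titles, context windows and references from the
#' cluster's vocabulary and reference pool, and \code{n_near_miss} near-miss
#' candidates drawing from a half-overlapping vocabulary with references from
#' unrelated pools.  Candidate ids are assigned through a seeded permutation
#' so that lexicographic tie-breaking never correlates with relevance.
#' Deterministic given the config (which includes the seed).
#'
#' @param config a [synth_config()].
#' @return list with \code{corpus} (a [corpus()]) and \code{qrels} (a
#'   [qrels()]).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  shared_vocab <- sprintf("common%03d", seq_len(cfg$shared_vocab_size))
  articles <- list()
  topics <- vector("list", cfg$n_topics)

  for (t in seq_len(cfg$n_topics)) {
    vocab <- sprintf("t%02dw%03d", t, seq_len(cfg$vocab_size))
    half <- cfg$vocab_size %/% 2L
    vocab_a <- vocab[seq_len(half)]              # "gene" half
    vocab_b <- vocab[(half + 1L):cfg$vocab_size] # "disease" half
    pool <- sprintf("pool-t%02d-r%03d", t, seq_len(cfg$reference_pool_size))

    n_cand <- (cfg$cluster_size - 1L) + cfg$n_near_miss
    cand_ids <- sprintf("T%02d-c%03d", t, sample.int(n_cand))
    target_id <- sprintf("T%02d-target", t)

    make_id <- function(i) if (i == 0L) target_id else cand_ids[i]
    cluster_idx <- seq_len(cfg$cluster_size - 1L)
    near_idx <- cfg$cluster_size - 1L + seq_len(cfg$n_near_miss)

    # target (i = 0) and highly related members draw on the full cluster
    # vocabulary; near-miss articles use only one half plus the shared block
    for (i in c(0L, cluster_idx, near_idx)) {
      aid <- make_id(i)
      is_member <- i <= cfg$cluster_size - 1L
      if (is_member) {
        title_src <- vocab
        window_src <- vocab
        overlap <- cfg$passage_overlap
        own_pool <- pool
        shared_p <- cfg$p_shared_reference
      } else {
        title_src <- c(if (i %% 2L == 0L) vocab_a else vocab_b, shared_vocab)
        window_src <- if (i %% 2L == 0L) vocab_a else vocab_b
        overlap <- cfg$passage_overlap
        # near-miss references come from other clusters' pools (or nowhere)
        other_t <- if (cfg$n_topics > 1L) {
          (t %% cfg$n_topics) + 1L
        } else {
          t
        }
        own_pool <- if (cfg$n_topics > 1L) {
          sprintf("pool-t%02d-r%03d", other_t,
                  seq_len(cfg$reference_pool_size))
        } else {
          character(0)
        }
        shared_p <- if (cfg$n_topics > 1L) cfg$p_shared_reference else 0
      }
      articles[[aid]] <- synth_article(
        aid, cfg, title_src, window_src, overlap, own_pool, shared_p,
        shared_vocab)
    }

    topics[[t]] <- list(
      topic_id = sprintf("topic%02d", t),
      target_id = target_id,
      candidate_ids = cand_ids,
      highly_related_ids = cand_ids[cluster_idx]
    )
  }
  list(corpus = corpus(unname(articles)), qrels = qrels(topics))
}

synth_article <- function(aid, cfg, title_src, window_src, overlap,
                          own_pool, shared_p, shared_vocab) {
  title_tokens <- sample(title_src, min(cfg$title_len, length(title_src)))

  # reference identities: a seeded mix of pool (shareable) and unique ids
  n_refs <- cfg$n_refs_per_article
  from_pool <- stats::rbinom(n_refs, 1L, shared_p) == 1L &
    length(own_pool) > 0L
  identities <- character(n_refs)
  if (any(from_pool)) {
    identities[from_pool] <- sample(own_pool, sum(from_pool))
  }
  identities[!from_pool] <- sprintf("uniq-%s-r%02d", aid,
                                    which(!from_pool))
  mention_counts <- sample.int(length(cfg$mention_count_probs), n_refs,
                               replace = TRUE,
                               prob = cfg$mention_count_probs)

  # abstract: a short sample of topical plus shared vocabulary
  abstract <- c(sample(title_src, min(8L, length(title_src))),
                sample(shared_vocab, 4L, replace = TRUE))
  body <- list(abstract)
  count <- length(abstract)
  abstract_span <- c(0L, count)

  # one window of window_len tokens before every mention; mentions are laid
  # out reference by reference so later references land later in the body
  mention_pos <- vector("list", n_refs)
  order_of_mention <- rep(seq_len(n_refs), mention_counts)
  for (k in order_of_mention) {
    from_topic <- stats::runif(cfg$window_len) < overlap
    window <- character(cfg$window_len)
    if (any(from_topic)) {
      window[from_topic] <- sample(window_src, sum(from_topic),
                                   replace = TRUE)
    }
    if (any(!from_topic)) {
      window[!from_topic] <- sprintf("%s-x%04d", aid,
                                     sample.int(9999L, sum(!from_topic)))
    }
    body[[length(body) + 1L]] <- window
    count <- count + cfg$window_len
    mention_pos[[k]] <- c(mention_pos[[k]], count)
  }
  body_tokens <- unlist(body, use.names = FALSE)

  # two sections splitting the post-abstract body; the second one is titled
  # so the section-based importance strategy has something to find
  mid <- abstract_span[2] +
    (length(body_tokens) - abstract_span[2]) %/% 2L
  sections <- list(
    article_section("Introduction", c(abstract_span[2], mid)),
    article_section("Results", c(mid, length(body_tokens)))
  )

  refs <- lapply(seq_len(n_refs), function(k) {
    article_reference(sprintf("ref%02d", k), identities[k],
                      sort(mention_pos[[k]]))
  })
  article(aid, title_tokens, body_tokens, abstract_span, sections, refs)
}
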
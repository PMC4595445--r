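#' PBC variant specification
#'
#' Canonical PBC scores a pair of references as 1 when they cite the same
#' work and as the Jaccard overlap of their context passages otherwise, then
#' weights the score by the mean citation importance of the two references.
#' The ablation variants keep the importance weighting and aggregation but
#' restrict the per-pair score: the link-only variant uses just the identity
#' match (1 or 0); the text-only variant always uses the passage Jaccard,
#' even for identical citations.
#'
#' @param importance_strategy one of \code{"frequency"} (canonical PBC),
#'   \code{"position"} (PBC-Pos) or \code{"section"} (PBC-Section).
#' @param link_component,text_component enable the identity branch and/or the
#'   passage-overlap branch; at least one must be enabled.
#'   \code{(frequency, TRUE, FALSE)} is PBC-link and
#'   \code{(frequency, FALSE, TRUE)} is PBC-text.
#' @return an object of class \code{pbc_variant}.
#' @export
pbc_variant <- function(importance_strategy = c("frequency", "position",
                                                "section"),
                        link_component = TRUE, text_component = TRUE) {
  if (!link_component && !text_component) {
    stop("at least one of link_component / text_component must be enabled")
  }
  structure(
    list(
      importance_strategy = match.arg(importance_strategy),
      link_component = isTRUE(link_component),
      text_component = isTRUE(text_component)
    ),
    class = "pbc_variant"
  )
}

# per-article reference profile: identity, context-passage set and importance
# for every reference, computed once per (article, alpha, strategy)
reference_profile <- function(art, alpha, strategy) {
  imp_of <- importance_fun(strategy)
  lapply(art$references, function(ref) {
    list(
      identity = ref$cited_article_id,
      cp = extract_context_passage(art, ref$ref_id, alpha),
      imp = imp_of(art, ref$ref_id)
    )
  })
}

jaccard <- function(a, b) {
  u <- length(unique(c(a, b)))
  if (u == 0L) {
    return(0)
  }
  length(intersect(a, b)) / u
}

pair_link_sim <- function(p1, p2, variant) {
  same <- !is.na(p1$identity) && !is.na(p2$identity) &&
    identical(p1$identity, p2$identity)
  if (variant$link_component && variant$text_component) {
    if (same) 1 else jaccard(p1$cp, p2$cp)
  } else if (variant$link_component) {
    if (same) 1 else 0
  } else {
    jaccard(p1$cp, p2$cp)
  }
}

#' Similarity between two references
#'
#' \code{link_sim} scores a pair of references in \code{[0, 1]}: 1 when they
#' resolve to the same cited work, otherwise the Jaccard overlap of their
#' context passages (see [extract_context_passage()]); unresolved identities
#' never match.  \code{link_sim_imp} weights it by the mean importance of the
#' two references, giving a value in \code{[0, 2]}.
#'
#' @param art1,art2 the citing [article()]s.
#' @param ref_id1,ref_id2 reference keys inside them.
#' @param alpha context-window size, see [extract_context_passage()].
#' @param variant a [pbc_variant()].
#' @return numeric scalar.
#' @export
link_sim <- function(art1, ref_id1, art2, ref_id2, alpha = 10L,
                     variant = pbc_variant()) {
  r1 <- find_reference(art1, ref_id1)
  r2 <- find_reference(art2, ref_id2)
  p1 <- list(identity = r1$cited_article_id,
             cp = extract_context_passage(art1, ref_id1, alpha))
  p2 <- list(identity = r2$cited_article_id,
             cp = extract_context_passage(art2, ref_id2, alpha))
  pair_link_sim(p1, p2, variant)
}

#' @rdname link_sim
#' @export
link_sim_imp <- function(art1, ref_id1, art2, ref_id2, alpha = 10L,
                         variant = pbc_variant()) {
  imp_of <- importance_fun(variant$importance_strategy)
  link_sim(art1, ref_id1, art2, ref_id2, alpha, variant) *
    (imp_of(art1, ref_id1) + imp_of(art2, ref_id2)) / 2
}

#' Passage-based bibliographic coupling between two articles
#'
#' Aggregates the weighted reference-pair similarities: every reference of
#' each article is matched to its best-scoring counterpart in the other
#' article, the two directed sums are added, and the total is divided by the
#' combined number of references.  The score lies in \code{[0, 2]} and is
#' symmetric.  If either article cites nothing the score is 0, matching the
#' convention used for plain bibliographic coupling.
#'
#' @param art1,art2 [article()]s.
#' @param alpha context-window size (default 10, the best-performing setting;
#'   use 15 for the section-based variant).
#' @param variant a [pbc_variant()].
#' @param cache optional environment from [similarity_cache()]; pairwise
#'   scores and per-article reference profiles are memoized there, keyed by
#'   the unordered article pair, alpha and variant, so repeated queries
#'   return identical values without recomputation.
#' @return numeric scalar in \code{[0, 2]}.
#' @export
pbc_similarity <- function(art1, art2, alpha = 10L,
                           variant = pbc_variant(), cache = NULL) {
  vkey <- paste(variant$importance_strategy,
                as.integer(variant$link_component),
                as.integer(variant$text_component), alpha, sep = "|")
  if (!is.null(cache)) {
    pkey <- paste(sort(c(art1$article_id, art2$article_id)), collapse = "||")
    skey <- paste0("score|", vkey, "|", pkey)
    hit <- cache$scores[[skey]]
    if (!is.null(hit)) {
      return(hit)
    }
  }
  prof1 <- cached_profile(art1, alpha, variant$importance_strategy, cache)
  prof2 <- cached_profile(art2, alpha, variant$importance_strategy, cache)
  score <- pbc_from_profiles(prof1, prof2, variant)
  if (!is.null(cache)) {
    cache$scores[[skey]] <- score
  }
  score
}

pbc_from_profiles <- function(prof1, prof2, variant) {
  n1 <- length(prof1)
  n2 <- length(prof2)
  if (n1 == 0L || n2 == 0L) {
    return(0)
  }
  m <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      m[i, j] <- pair_link_sim(prof1[[i]], prof2[[j]], variant) *
        (prof1[[i]]$imp + prof2[[j]]$imp) / 2
    }
  }
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (n1 + n2)
}

#' @rdname pbc_similarity
#' @export
similarity_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$scores <- new.env(parent = emptyenv())
  cache$profiles <- new.env(parent = emptyenv())
  cache
}

cached_profile <- function(art, alpha, strategy, cache) {
  if (is.null(cache)) {
    return(reference_profile(art, alpha, strategy))
  }
  key <- paste0("profile|", art$article_id, "|", alpha, "|", strategy)
  hit <- cache$profiles[[key]]
  if (is.null(hit)) {
    hit <- reference_profile(art, alpha, strategy)
    cache$profiles[[key]] <- hit
  }
  hit
}

measure_catalog <- function() {
  c("PBC", "PBC-Pos", "PBC-Section", "PBC-link", "PBC-text", "BC",
    "OK-TitleAbstract", "OK-WholeArticle")
}

measure_variant <- function(measure) {
  switch(measure,
         "PBC" = pbc_variant("frequency"),
         "PBC-Pos" = pbc_variant("position"),
         "PBC-Section" = pbc_variant("section"),
         "PBC-link" = pbc_variant("frequency", TRUE, FALSE),
         "PBC-text" = pbc_variant("frequency", FALSE, TRUE),
         NULL)
}

#' Rank candidate articles against a target
#'
#' Scores every candidate with the chosen similarity measure and orders them
#' by descending score, breaking ties by ascending candidate id so a run is
#' fully deterministic.
#'
#' @param target_art the target [article()].
#' @param candidate_arts list of candidate [article()]s.
#' @param measure one of \code{"PBC"}, \code{"PBC-Pos"}, \code{"PBC-Section"},
#'   \code{"PBC-link"}, \code{"PBC-text"}, \code{"BC"},
#'   \code{"OK-TitleAbstract"}, \code{"OK-WholeArticle"}, or
#'   \code{"external"} (recorded scores supplied via \code{external_scores},
#'   e.g. similarity values computed by a system outside this package).
#' @param alpha context-window size for the PBC family.
#' @param corpus_stats a [build_corpus_stats()] result, required for the OK
#'   measures (its field view must match the measure).
#' @param bm25 a [bm25_params()] for the OK measures.
#' @param external_scores named numeric vector of candidate scores, required
#'   for \code{measure = "external"}; unlisted candidates are appended after
#'   all scored ones, lowest-ranked, in ascending id order.
#' @param topic_id,measure_name labels carried into the run.
#' @param cache optional [similarity_cache()].
#' @return an object of class \code{run_ranking}: list with \code{topic_id},
#'   \code{target_id}, \code{measure_name} and a data frame \code{ranking}
#'   with columns \code{candidate_id}, \code{score}, \code{rank}.
#' @export
rank_candidates <- function(target_art, candidate_arts, measure = "PBC",
                            alpha = 10L, corpus_stats = NULL,
                            bm25 = bm25_params(), external_scores = NULL,
                            topic_id = NA_character_, measure_name = measure,
                            cache = NULL) {
  ids <- vapply(candidate_arts, function(a) a$article_id, character(1))
  if (identical(measure, "external")) {
    if (is.null(external_scores) || is.null(names(external_scores))) {
      stop("measure 'external' requires a named external_scores vector")
    }
    scores <- external_scores[ids]
    # candidates without a recorded score are ranked below every scored one
    scores[is.na(scores)] <- -Inf
    names(scores) <- ids
  } else if (identical(measure, "BC")) {
    scores <- vapply(candidate_arts, function(a) {
      bc_similarity(target_art, a)
    }, numeric(1))
  } else if (measure %in% c("OK-TitleAbstract", "OK-WholeArticle")) {
    if (is.null(corpus_stats)) {
      stop("measure '", measure, "' requires corpus_stats")
    }
    scores <- vapply(candidate_arts, function(a) {
      ok_similarity(target_art, a, corpus_stats, bm25)
    }, numeric(1))
  } else {
    variant <- measure_variant(measure)
    if (is.null(variant)) {
      stop("unknown measure '", measure, "'; expected one of: ",
           paste(c(measure_catalog(), "external"), collapse = ", "))
    }
    scores <- vapply(candidate_arts, function(a) {
      pbc_similarity(target_art, a, alpha, variant, cache)
    }, numeric(1))
  }
  names(scores) <- ids
  ranking_from_scores(scores, topic_id, target_art$article_id, measure_name)
}

ranking_from_scores <- function(scores, topic_id, target_id, measure_name) {
  ids <- names(scores)
  ord <- order(-scores, ids, method = "radix")
  df <- data.frame(
    candidate_id = ids[ord],
    score = unname(scores[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  structure(
    list(topic_id = as.character(topic_id),
         target_id = as.character(target_id),
         measure_name = as.character(measure_name),
         ranking = df),
    class = "run_ranking"
  )
}

#' @export
print.run_ranking <- function(x, ...) {
  cat("<run_ranking>", x$measure_name, "topic", x$topic_id, "-",
      nrow(x$ranking), "candidates\n")
  invisible(x)
}

#' Read / write run files
#'
#' A run file is tab-separated text with columns \code{topic_id},
#' \code{target_id}, \code{candidate_id}, \code{rank}, \code{score},
#' \code{measure_name}; one row per ranked candidate, stable across runs.
#'
#' @param runs list of \code{run_ranking} objects.
#' @param path file path.
#' @return \code{read_run_file} returns a list of \code{run_ranking} objects
#'   (one per topic/measure combination present in the file).
#' @export
write_run_file <- function(runs, path) {
  if (inherits(runs, "run_ranking")) {
    runs <- list(runs)
  }
  rows <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      topic_id = r$topic_id,
      target_id = r$target_id,
      candidate_id = r$ranking$candidate_id,
      rank = r$ranking$rank,
      score = r$ranking$score,
      measure_name = r$measure_name,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_file
#' @export
read_run_file <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(score = "numeric", rank = "integer"),
                          stringsAsFactors = FALSE)
  need <- c("topic_id", "target_id", "candidate_id", "rank", "score",
            "measure_name")
  if (!all(need %in% names(df))) {
    stop("run file must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$topic_id, df$measure_name, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    structure(
      list(topic_id = d$topic_id[1], target_id = d$target_id[1],
           measure_name = d$measure_name[1],
           ranking = data.frame(candidate_id = d$candidate_id,
                                score = d$score, rank = d$rank,
                                stringsAsFactors = FALSE)),
      class = "run_ranking")
  })
}
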
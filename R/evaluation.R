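complete_ranking <- function(ranked_ids, relevant_ids) {
  # relevant articles a system never scored are effectively ranked lowest:
  # append them after every scored candidate, in ascending id order
  missing <- sort(setdiff(relevant_ids, ranked_ids))
  c(ranked_ids, missing)
}

ranked_ids_of <- function(ranking) {
  if (inherits(ranking, "run_ranking")) {
    ranking$ranking$candidate_id
  } else {
    as.character(ranking)
  }
}

#' Average precision of one ranking
#'
#' For the \code{k} relevant items of a topic, the average of \code{j /
#' Arc(j)} where \code{Arc(j)} is the rank position of the \code{j}-th
#' relevant item (ties already broken deterministically: descending score,
#' then ascending id).  Relevant items missing from the ranking are appended
#' after all ranked candidates.  With \code{ties = "pessimistic"},
#' \code{Arc(j)} instead counts every candidate whose score is greater than
#' or equal to that relevant item's score, which penalizes score ties; this
#' requires a \code{run_ranking} input carrying scores.
#'
#' @param ranking a \code{run_ranking} or a character vector of candidate ids
#'   in rank order.
#' @param relevant_ids non-empty character vector of relevant candidate ids.
#' @param ties \code{"rank"} (default) or \code{"pessimistic"}.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
average_precision <- function(ranking, relevant_ids,
                              ties = c("rank", "pessimistic")) {
  ties <- match.arg(ties)
  relevant_ids <- as.character(relevant_ids)
  if (length(relevant_ids) == 0L) {
    stop("average precision is undefined for an empty relevant set")
  }
  ids <- complete_ranking(ranked_ids_of(ranking), relevant_ids)
  pos <- sort(match(relevant_ids, ids))
  if (anyNA(pos)) {
    stop("internal error: relevant id missing after completion")
  }
  if (ties == "pessimistic") {
    if (!inherits(ranking, "run_ranking")) {
      stop("ties = 'pessimistic' requires a run_ranking with scores")
    }
    scores <- c(ranking$ranking$score,
                rep(-Inf, length(ids) - nrow(ranking$ranking)))
    arc <- vapply(pos, function(p) sum(scores >= scores[p]), numeric(1))
  } else {
    arc <- pos
  }
  mean(seq_along(pos) / arc)
}

#' Mean average precision
#'
#' @param ap_values numeric vector of per-topic average precisions (>= 1).
#' @return their arithmetic mean.
#' @export
mean_average_precision <- function(ap_values) {
  ap_values <- as.numeric(ap_values)
  if (length(ap_values) == 0L) {
    stop("MAP is undefined over zero topics")
  }
  mean(ap_values)
}

#' Precision at a rank cutoff
#'
#' Fraction of the top-\code{x} ranked candidates that are relevant.
#'
#' @inheritParams average_precision
#' @param x positive integer cutoff.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
precision_at_x <- function(ranking, relevant_ids, x) {
  x <- as.integer(x)
  if (is.na(x) || x < 1L) {
    stop("x must be a positive integer")
  }
  ids <- complete_ranking(ranked_ids_of(ranking), as.character(relevant_ids))
  top <- ids[seq_len(min(x, length(ids)))]
  sum(top %in% relevant_ids) / x
}

topic_relevants <- function(qr, topic_id) {
  tp <- qr$topics[[topic_id]]
  if (is.null(tp)) {
    stop("topic '", topic_id, "' not found in qrels")
  }
  tp$highly_related_ids
}

#' Topic-averaged precision at a cutoff, and the fraction of topics hit
#'
#' \code{average_p_at_x} averages [precision_at_x()] over topics;
#' \code{pairs_hit_fraction} reports the fraction of topics whose top-\code{x}
#' contains at least one relevant article (P@x strictly positive), i.e. the
#' share of retrieval tasks where reading only \code{x} recommendations finds
#' something relevant.
#'
#' @param runs list of \code{run_ranking} objects, one per topic (a single
#'   measure).
#' @param qr a [qrels()] object supplying each topic's relevant ids.
#' @param x positive integer cutoff.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
average_p_at_x <- function(runs, qr, x) {
  if (length(runs) == 0L) {
    stop("no topics to average over")
  }
  mean(vapply(runs, function(r) {
    precision_at_x(r, topic_relevants(qr, r$topic_id), x)
  }, numeric(1)))
}

#' @rdname average_p_at_x
#' @export
pairs_hit_fraction <- function(runs, qr, x) {
  if (length(runs) == 0L) {
    stop("no topics to summarize")
  }
  mean(vapply(runs, function(r) {
    precision_at_x(r, topic_relevants(qr, r$topic_id), x) > 0
  }, logical(1)))
}

#' Two-sided paired t-test on per-topic metric vectors
#'
#' Compares two systems on the same topics.  Degenerate difference vectors
#' are handled explicitly: all-zero differences give \code{p = 1} (no
#' evidence of any difference), and a constant non-zero difference (zero
#' variance) gives \code{p = 0} with \code{degenerate = TRUE} rather than a
#' division by zero.
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 2) of a
#'   per-topic metric for two systems.
#' @param conf_level significance threshold for the \code{significant} flag.
#' @return list with \code{p_value}, \code{statistic}, \code{significant},
#'   \code{degenerate}.
#' @export
paired_t_test <- function(values_a, values_b, conf_level = 0.95) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length")
  }
  if (length(a) < 2L) {
    stop("paired t-test needs at least two topics")
  }
  d <- a - b
  alpha_level <- 1 - conf_level
  eps <- .Machine$double.eps^0.5
  if (all(abs(d) < eps)) {
    return(list(p_value = 1, statistic = 0, significant = FALSE,
                degenerate = FALSE))
  }
  # constant non-zero differences have (numerically) zero variance
  if (stats::sd(d) < eps * max(abs(d))) {
    return(list(p_value = 0, statistic = sign(d[1]) * Inf,
                significant = TRUE, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       significant = unname(tt$p.value) < alpha_level, degenerate = FALSE)
}

#' Evaluate a set of runs against relevance judgments
#'
#' Computes per-topic average precision and P@x for every measure present in
#' \code{runs}, aggregates them into MAP, topic-averaged P@x and the fraction
#' of topics with P@x > 0, and runs pairwise two-sided paired t-tests between
#' all measure pairs on AP and each P@x.
#'
#' @param runs list of \code{run_ranking} objects (any mix of measures; each
#'   measure must cover the same topics).
#' @param qr a [qrels()] object.
#' @param x_values integer cutoffs for P@x.
#' @param ties passed to [average_precision()].
#' @return an object of class \code{eval_report}: list with
#'   \code{per_topic} (data frame: measure, topic_id, ap, p_at_<x>...),
#'   \code{aggregate} (data frame: measure, map, avg_p_at_<x>...,
#'   hit_at_<x>...), and \code{significance} (data frame: measure_a,
#'   measure_b, metric, p_value, significant, degenerate).
#' @export
evaluate_runs <- function(runs, qr, x_values = c(1L, 3L, 5L),
                          ties = "rank") {
  stopifnot(inherits(qr, "pbc_qrels"))
  if (length(runs) == 0L) {
    stop("no runs to evaluate")
  }
  x_values <- sort(unique(as.integer(x_values)))
  per_topic <- do.call(rbind, lapply(runs, function(r) {
    rel <- topic_relevants(qr, r$topic_id)
    row <- data.frame(
      measure = r$measure_name, topic_id = r$topic_id,
      ap = average_precision(r, rel, ties = ties),
      stringsAsFactors = FALSE
    )
    for (x in x_values) {
      row[[paste0("p_at_", x)]] <- precision_at_x(r, rel, x)
    }
    row
  }))
  rownames(per_topic) <- NULL
  measures <- unique(per_topic$measure)
  per_topic <- per_topic[order(match(per_topic$measure, measures),
                               per_topic$topic_id), , drop = FALSE]

  aggregate <- do.call(rbind, lapply(measures, function(m) {
    d <- per_topic[per_topic$measure == m, , drop = FALSE]
    row <- data.frame(measure = m, map = mean(d$ap),
                      stringsAsFactors = FALSE)
    for (x in x_values) {
      col <- paste0("p_at_", x)
      row[[paste0("avg_", col)]] <- mean(d[[col]])
      row[[paste0("hit_at_", x)]] <- mean(d[[col]] > 0)
    }
    row
  }))
  rownames(aggregate) <- NULL

  significance <- NULL
  metrics <- c("ap", paste0("p_at_", x_values))
  if (length(measures) >= 2L && nrow(per_topic) > 0L) {
    pairs <- utils::combn(measures, 2, simplify = FALSE)
    significance <- do.call(rbind, lapply(pairs, function(pr) {
      da <- per_topic[per_topic$measure == pr[1], , drop = FALSE]
      db <- per_topic[per_topic$measure == pr[2], , drop = FALSE]
      db <- db[match(da$topic_id, db$topic_id), , drop = FALSE]
      if (anyNA(db$topic_id)) {
        stop("measures '", pr[1], "' and '", pr[2],
             "' do not cover the same topics")
      }
      do.call(rbind, lapply(metrics, function(met) {
        if (nrow(da) < 2L) {
          return(NULL)
        }
        tt <- paired_t_test(da[[met]], db[[met]])
        data.frame(measure_a = pr[1], measure_b = pr[2], metric = met,
                   p_value = tt$p_value, significant = tt$significant,
                   degenerate = tt$degenerate, stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(significance)) rownames(significance) <- NULL
  }

  structure(
    list(per_topic = per_topic, aggregate = aggregate,
         significance = significance, x_values = x_values),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Ranked-retrieval evaluation over",
      length(unique(x$per_topic$topic_id)), "topics\n\n")
  agg <- x$aggregate
  num <- vapply(agg, is.numeric, logical(1))
  agg[num] <- lapply(agg[num], round, digits = digits)
  print(agg, row.names = FALSE)
  if (!is.null(x$significance)) {
    sig <- x$significance[x$significance$significant, , drop = FALSE]
    cat("\nSignificant paired differences (p < 0.05):",
        nrow(sig), "of", nrow(x$significance), "tests\n")
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluate_runs()] result.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(
    aggregate = report$aggregate,
    per_topic = report$per_topic,
    significance = report$significance
  )
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(path)
}

# columns expected in the extracted supplementary similarity table
s1_measure_columns <- function() {
  c("PBC", "PBC-Pos", "PBC-Section", "BC", "OK-TitleAbstract",
    "OK-WholeArticle", "HybridK50-TitleAbstract", "HybridK50-WholeArticle")
}

#' Load a recorded-similarity table (supplementary-run layout)
#'
#' Reads a tab-separated table with one row per (topic, candidate) pair:
#' columns \code{topic_id}, \code{target_id}, \code{candidate_id},
#' \code{highly_related} (0/1), and one numeric column per recorded measure
#' (\code{PBC}, \code{PBC-Pos}, \code{PBC-Section}, \code{BC},
#' \code{OK-TitleAbstract}, \code{OK-WholeArticle},
#' \code{HybridK50-TitleAbstract}, \code{HybridK50-WholeArticle}).  Such a
#' table is the plain-text form of the per-candidate similarity values a
#' study archives alongside its article ids; the original archive must be
#' extracted to this layout first.  Rankings are rebuilt per topic and
#' measure with the deterministic tie rule; topics without any
#' highly-related row are dropped with a warning.
#'
#' @param path tab-separated file in the layout above.
#' @return list with \code{qrels} (a [qrels()]) and \code{runs} (named list:
#'   measure -> list of \code{run_ranking}, one per topic).
#' @export
load_s1_run <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("topic_id", "target_id", "candidate_id", "highly_related",
            s1_measure_columns())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("recorded-run table schema error: missing column(s) ",
         paste(missing, collapse = ", "), "; detected headers: ",
         paste(names(df), collapse = ", "))
  }
  df$topic_id <- as.character(df$topic_id)
  df$candidate_id <- as.character(df$candidate_id)
  df$target_id <- as.character(df$target_id)

  topic_split <- split(df, factor(df$topic_id, levels = unique(df$topic_id)))
  keep <- vapply(topic_split, function(d) any(d$highly_related == 1),
                 logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep),
            " topic(s) without any highly related candidate: ",
            paste(names(topic_split)[!keep], collapse = ", "))
    topic_split <- topic_split[keep]
  }
  if (length(topic_split) == 0L) {
    stop("no usable topics in recorded-run table")
  }

  qr <- qrels(lapply(unname(topic_split), function(d) {
    list(topic_id = d$topic_id[1], target_id = d$target_id[1],
         candidate_ids = d$candidate_id,
         highly_related_ids = d$candidate_id[d$highly_related == 1])
  }))
  runs <- lapply(s1_measure_columns(), function(m) {
    lapply(unname(topic_split), function(d) {
      scores <- stats::setNames(as.numeric(d[[m]]), d$candidate_id)
      ranking_from_scores(scores, d$topic_id[1], d$target_id[1], m)
    })
  })
  names(runs) <- s1_measure_columns()
  list(qrels = qr, runs = runs)
}
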
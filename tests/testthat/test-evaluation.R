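test_that("average precision reproduces hand-evaluated rankings", {
  expect_equal(average_precision(c("a", "b", "c"), "a"), 1)
  expect_equal(average_precision(c("a", "b", "c", "d"), c("a", "c")),
               (1 / 1 + 2 / 3) / 2)
  expect_equal(average_precision(c("x", "y", "z", "a"), "a"), 0.25)
  expect_error(average_precision(c("a", "b"), character(0)), "empty")
})

test_that("relevant items missing from a ranking are appended last in id
           order", {
  # ranked: n1 n2; relevants b, a unranked -> effective ranks 3 (a) and 4 (b)
  expect_equal(average_precision(c("n1", "n2"), c("b", "a")),
               (1 / 3 + 2 / 4) / 2)
  expect_equal(precision_at_x(c("n1", "n2"), c("b", "a"), 3), 1 / 3)
})

test_that("MAP is the mean of per-topic average precisions", {
  expect_equal(mean_average_precision(c(1, 0.5)), 0.75)
  expect_equal(mean_average_precision(rep(1, 5)), 1)
  expect_equal(mean_average_precision(0.37), 0.37)
  expect_error(mean_average_precision(numeric(0)), "zero topics")
})

test_that("precision at x counts relevants among the top x", {
  expect_equal(precision_at_x(c("a", "b", "r", "s"), c("a", "r"), 3), 2 / 3)
  expect_equal(precision_at_x(c("r", "b"), "r", 1), 1)
  expect_equal(precision_at_x(c("a", "b", "c"), "z1", 3), 0)
  expect_error(precision_at_x(c("a"), "a", 0), "positive")
})

test_that("rank-based metrics depend only on relevant item positions", {
  set.seed(61)
  rel <- c("r1", "r2")
  base <- c("n1", "r1", "n2", "n3", "r2", "n4")
  ap0 <- average_precision(base, rel)
  p0 <- precision_at_x(base, rel, 3)
  for (i in 1:10) {
    nonrel <- setdiff(base, rel)
    shuffled <- base
    shuffled[!(base %in% rel)] <- sample(nonrel)
    expect_equal(average_precision(shuffled, rel), ap0)
    expect_equal(precision_at_x(shuffled, rel, 3), p0)
  }
})

test_that("AP equals 1 exactly when relevants fill the top ranks, and
           never decreases when a relevant moves up", {
  set.seed(62)
  ids <- sprintf("c%02d", 1:8)
  for (trial in 1:25) {
    ranked <- sample(ids)
    rel <- sample(ids, sample(1:4, 1))
    ap <- average_precision(ranked, rel)
    top <- ranked[seq_along(rel)]
    expect_identical(ap == 1, setequal(top, rel))
    # swap the first relevant up one place: AP must not decrease
    pos <- which(ranked %in% rel)[1]
    if (pos > 1) {
      moved <- ranked
      moved[c(pos - 1, pos)] <- moved[c(pos, pos - 1)]
      expect_gte(average_precision(moved, rel), ap)
    }
  }
})

test_that("AP matches exhaustive brute-force scoring on short rankings", {
  set.seed(63)
  for (n in 2:8) {
    ids <- sprintf("c%d", 1:n)
    for (trial in 1:10) {
      ranked <- sample(ids)
      rel <- sample(ids, sample(seq_len(n), 1))
      expect_equal(average_precision(ranked, rel), oracle_ap(ranked, rel))
    }
  }
})

test_that("pessimistic tie handling counts all score-tied competitors", {
  scores <- c(a = 0.9, b = 0.9, r = 0.9, z = 0.1)
  rr <- pbcouple:::ranking_from_scores(scores, "t", "T", "m")
  # deterministic tie-break ranks r third; pessimistic mode charges it for
  # all three tied items either way
  expect_equal(average_precision(rr, "r"), 1 / 3)
  expect_equal(average_precision(rr, "r", ties = "pessimistic"), 1 / 3)
  scores2 <- c(r = 0.9, s = 0.9, z = 0.1)
  rr2 <- pbcouple:::ranking_from_scores(scores2, "t", "T", "m")
  expect_equal(average_precision(rr2, "r"), 1)      # r wins the tie by id
  expect_equal(average_precision(rr2, "r", ties = "pessimistic"), 1 / 2)
})

test_that("topic-level aggregation: averaged P@x and fraction of topics
           hit", {
  qr <- qrels(list(
    list(topic_id = "t1", target_id = "T1",
         candidate_ids = c("a", "b", "c", "d"), highly_related_ids = "a"),
    list(topic_id = "t2", target_id = "T2",
         candidate_ids = c("e", "f", "g", "h"), highly_related_ids = "e"),
    list(topic_id = "t3", target_id = "T3",
         candidate_ids = c("i", "j", "k", "l"), highly_related_ids = "i"),
    list(topic_id = "t4", target_id = "T4",
         candidate_ids = c("m", "n", "o", "p"), highly_related_ids = "m")
  ))
  mk <- function(topic, ordered) {
    pbcouple:::ranking_from_scores(
      stats::setNames(rev(seq_along(ordered)), ordered), topic, "T", "m")
  }
  runs <- list(mk("t1", c("a", "b", "c", "d")),   # hit at rank 1
               mk("t2", c("f", "e", "g", "h")),   # hit at rank 2
               mk("t3", c("j", "k", "i", "l")),   # hit at rank 3
               mk("t4", c("n", "o", "p", "m")))   # miss in top 3
  expect_equal(average_p_at_x(runs, qr, 1), 1 / 4)
  expect_equal(average_p_at_x(runs, qr, 3), (1 + 1 + 1 + 0) / 3 / 4)
  expect_equal(pairs_hit_fraction(runs, qr, 1), 0.25)
  expect_equal(pairs_hit_fraction(runs, qr, 3), 0.75)
  expect_equal(pairs_hit_fraction(runs, qr, 4), 1)
  expect_equal(pairs_hit_fraction(runs[1:2], qr, 1), 0.5)
})

test_that("paired t-test: textbook case, degenerate conventions, and
           symmetry", {
  # identical vectors: no difference, p = 1 by convention
  same <- paired_t_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # constant non-zero difference: zero variance, flagged degenerate
  degen <- paired_t_test(c(0.1, 0.2, 0.3, 0.4), c(0.2, 0.3, 0.4, 0.5))
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
  # non-degenerate case agrees with the closed-form paired statistic
  a <- c(0.9, 0.5, 0.7, 0.3, 0.8)
  b <- c(0.6, 0.4, 0.5, 0.4, 0.5)
  d <- a - b
  tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  got <- paired_t_test(a, b)
  expect_equal(got$p_value, p_manual)
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$p_value, got$p_value)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("evaluate_runs assembles per-topic and aggregate metrics
           coherently", {
  gen <- generate_corpus(synth_config(n_topics = 4, n_near_miss = 6,
                                      seed = 3))
  runs <- rank_all_topics(gen$corpus, gen$qrels, measures = c("PBC", "BC"))
  rep <- evaluate_runs(unlist(unname(runs), recursive = FALSE), gen$qrels)
  expect_setequal(rep$aggregate$measure, c("PBC", "BC"))
  for (m in c("PBC", "BC")) {
    d <- rep$per_topic[rep$per_topic$measure == m, ]
    expect_equal(rep$aggregate$map[rep$aggregate$measure == m], mean(d$ap))
  }
  num_cols <- vapply(rep$aggregate, is.numeric, logical(1))
  vals <- unlist(rep$aggregate[num_cols])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(c("ap", "p_at_1", "p_at_3", "p_at_5") %in%
                    names(rep$per_topic)))
  expect_equal(nrow(rep$significance), 4)  # one pair x {ap, p@1, p@3, p@5}
})

s1_table <- function(path) {
  measures <- c("PBC", "PBC-Pos", "PBC-Section", "BC", "OK-TitleAbstract",
                "OK-WholeArticle", "HybridK50-TitleAbstract",
                "HybridK50-WholeArticle")
  set.seed(99)
  rows <- do.call(rbind, lapply(c("g1", "g2"), function(tp) {
    d <- data.frame(topic_id = tp, target_id = paste0(tp, "-target"),
                    candidate_id = paste0(tp, "-c", 1:5),
                    highly_related = c(1, 0, 0, 1, 0))
    for (m in measures) d[[m]] <- round(stats::runif(5), 3)
    d
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows
}

test_that("recorded-similarity tables load into eight runs per topic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- s1_table(path)
  loaded <- load_s1_run(path)
  expect_length(loaded$runs, 8)
  expect_length(loaded$runs$PBC, 2)
  expect_length(loaded$qrels$topics, 2)
  # rankings follow the recorded scores with the deterministic tie rule
  r <- loaded$runs$BC[[1]]
  d <- rows[rows$topic_id == "g1", ]
  want <- d$candidate_id[order(-d$BC, d$candidate_id)]
  expect_identical(r$ranking$candidate_id, want)
  # evaluating the loaded runs works end to end
  rep <- evaluate_runs(unlist(unname(loaded$runs), recursive = FALSE),
                       loaded$qrels)
  expect_equal(nrow(rep$aggregate), 8)
})

test_that("recorded-table schema errors and empty topics are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- s1_table(path)
  rows$BC <- NULL
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_s1_run(path), "missing column.*BC")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  rows2 <- s1_table(path2)
  rows2$highly_related[rows2$topic_id == "g2"] <- 0
  utils::write.table(rows2, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(loaded <- load_s1_run(path2), "dropping 1 topic")
  expect_length(loaded$qrels$topics, 1)
})
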
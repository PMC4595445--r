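#' Rank every topic of a qrels with one or more measures
#'
#' Convenience driver for whole-benchmark runs: for each topic, scores the
#' topic's candidate pool against its target with every requested measure.
#' Collection statistics for the OK measures are built once over the
#' evaluation corpus (every target and candidate).  A shared similarity
#' cache makes the PBC family compute each article profile once.
#'
#' @param corp a [corpus()] holding all targets and candidates.
#' @param qr a [qrels()].
#' @param measures character vector of measure names accepted by
#'   [rank_candidates()] (excluding \code{"external"}).
#' @param alpha context-window size for the PBC family; the section-based
#'   variant uses \code{alpha_section} instead (its best-performing window is
#'   a little wider).
#' @param alpha_section window size for \code{"PBC-Section"} (default 15).
#' @param bm25 a [bm25_params()].
#' @return named list: measure name -> list of \code{run_ranking} objects,
#'   one per topic.
#' @export
rank_all_topics <- function(corp, qr, measures = "PBC", alpha = 10L,
                            alpha_section = 15L, bm25 = bm25_params()) {
  stopifnot(inherits(corp, "pbc_corpus"), inherits(qr, "pbc_qrels"))
  needs_stats <- measures[startsWith(measures, "OK-")]
  stats_by_view <- list()
  for (m in needs_stats) {
    view <- if (m == "OK-TitleAbstract") "title_abstract" else "whole_article"
    if (is.null(stats_by_view[[view]])) {
      stats_by_view[[view]] <- build_corpus_stats(corp, view)
    }
  }
  cache <- similarity_cache()
  out <- lapply(measures, function(m) {
    a <- if (m == "PBC-Section") alpha_section else alpha
    view <- if (m == "OK-TitleAbstract") "title_abstract" else
      "whole_article"
    lapply(unname(qr$topics), function(tp) {
      target <- corpus_article(corp, tp$target_id)
      cands <- lapply(tp$candidate_ids, corpus_article, corp = corp)
      rank_candidates(target, cands, measure = m, alpha = a,
                      corpus_stats = stats_by_view[[view]], bm25 = bm25,
                      topic_id = tp$topic_id, cache = cache)
    })
  })
  names(out) <- measures
  out
}

cli_usage <- function() {
  paste(
    "usage: pbcouple <command> [options]",
    "",
    "commands:",
    "  synth    generate a synthetic corpus + qrels",
    "           --seed INT --n-topics INT --cluster-size INT",
    "           --n-near-miss INT --p-shared-reference NUM",
    "           --passage-overlap NUM --out-corpus FILE --out-qrels FILE",
    "  ingest   read JATS/NXML files into the JSON corpus dialect",
    "           --nxml FILE[,FILE...] --out FILE",
    "  rank     score one measure over all topics",
    "           --corpus FILE --qrels FILE --measure NAME [--alpha INT]",
    "           [--alpha-section INT] [--k1 NUM] [--b NUM] --out FILE",
    "  eval     evaluate run files against qrels",
    "           --run FILE[,FILE...] --qrels FILE [--x 1,3,5] --out FILE",
    "  s1-eval  evaluate a recorded-similarity table",
    "           --table FILE [--x 1,3,5] --out FILE",
    sep = "\n"
  )
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[[i]]
    if (!startsWith(key, "--")) {
      stop("unexpected argument '", key, "'")
    }
    if (i + 1L > length(argv)) {
      stop("missing value for option ", key)
    }
    opts[[substring(key, 3L)]] <- argv[[i + 1L]]
    i <- i + 2L
  }
  opts
}

opt_or <- function(opts, name, default) {
  if (is.null(opts[[name]])) default else opts[[name]]
}

write_provenance <- function(out_path, command, opts) {
  record <- list(
    command = command,
    options = opts,
    package = "pbcouple",
    version = as.character(utils::packageVersion("pbcouple")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(record, paste0(out_path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Command-line entry point
#'
#' Implements the subcommands of the shipped CLI script
#' (\code{inst/cli/pbcouple.R}): \code{synth}, \code{ingest}, \code{rank},
#' \code{eval}, \code{s1-eval}.  Every run writes a provenance record
#' (command, options, package version) beside its primary output.  Identical
#' inputs and options produce identical outputs.  On any validation failure a
#' single-line \code{error: ...} message goes to standard error and the
#' return value is 1; logging goes to standard error so results on standard
#' output stay scriptable.
#'
#' @param argv character vector of command-line arguments (the subcommand
#'   followed by \code{--option value} pairs).
#' @return integer exit status, 0 on success.
#' @export
run_command <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0L) {
      message(cli_usage())
      return(1L)
    }
    command <- argv[[1]]
    opts <- parse_cli_args(argv[-1])
    switch(command,
           synth = cli_synth(opts),
           ingest = cli_ingest(opts),
           rank = cli_rank(opts),
           eval = cli_eval(opts),
           "s1-eval" = cli_s1_eval(opts),
           stop("unknown command '", command, "'"))
    0L
  }, error = function(e) {
    message("error: ", gsub("[\r\n]+", " ", conditionMessage(e)))
    1L
  })
  status
}

require_opt <- function(opts, name) {
  val <- opts[[name]]
  if (is.null(val)) {
    stop("missing required option --", name)
  }
  val
}

cli_synth <- function(opts) {
  cfg <- synth_config(
    n_topics = as.integer(opt_or(opts, "n-topics", 20L)),
    cluster_size = as.integer(opt_or(opts, "cluster-size", 4L)),
    n_near_miss = as.integer(opt_or(opts, "n-near-miss", 30L)),
    p_shared_reference = as.numeric(
      opt_or(opts, "p-shared-reference", 0.5)),
    passage_overlap = as.numeric(opt_or(opts, "passage-overlap", 0.6)),
    seed = as.integer(opt_or(opts, "seed", 1L))
  )
  out_corpus <- require_opt(opts, "out-corpus")
  out_qrels <- require_opt(opts, "out-qrels")
  gen <- generate_corpus(cfg)
  write_corpus_json(gen$corpus, out_corpus)
  write_qrels(gen$qrels, out_qrels)
  write_provenance(out_corpus, "synth", opts)
  message("synth: ", length(gen$corpus$articles), " articles, ",
          length(gen$qrels$topics), " topics")
}

cli_ingest <- function(opts) {
  paths <- strsplit(require_opt(opts, "nxml"), ",")[[1]]
  arts <- lapply(paths, read_jats_article)
  out <- require_opt(opts, "out")
  write_corpus_json(corpus(arts), out)
  write_provenance(out, "ingest", opts)
  message("ingest: ", length(arts), " article(s)")
}

cli_rank <- function(opts) {
  corp <- read_corpus_json(require_opt(opts, "corpus"))
  qr <- read_qrels(require_opt(opts, "qrels"))
  measure <- require_opt(opts, "measure")
  if (!(measure %in% measure_catalog())) {
    stop("unknown measure '", measure, "'; expected one of: ",
         paste(measure_catalog(), collapse = ", "))
  }
  runs <- rank_all_topics(
    corp, qr, measures = measure,
    alpha = as.integer(opt_or(opts, "alpha", 10L)),
    alpha_section = as.integer(opt_or(opts, "alpha-section", 15L)),
    bm25 = bm25_params(k1 = as.numeric(opt_or(opts, "k1", 8)),
                       b = as.numeric(opt_or(opts, "b", 1.0)))
  )
  out <- require_opt(opts, "out")
  write_run_file(runs[[measure]], out)
  write_provenance(out, "rank", opts)
  message("rank: ", measure, " over ", length(runs[[measure]]), " topics")
}

cli_eval <- function(opts) {
  run_paths <- strsplit(require_opt(opts, "run"), ",")[[1]]
  runs <- unlist(lapply(run_paths, read_run_file), recursive = FALSE)
  qr <- read_qrels(require_opt(opts, "qrels"))
  x_values <- as.integer(strsplit(opt_or(opts, "x", "1,3,5"), ",")[[1]])
  report <- evaluate_runs(runs, qr, x_values = x_values)
  out <- require_opt(opts, "out")
  write_eval_report(report, out)
  write_provenance(out, "eval", opts)
  message("eval: ", nrow(report$aggregate), " measure(s), ",
          length(unique(report$per_topic$topic_id)), " topics")
}

cli_s1_eval <- function(opts) {
  loaded <- load_s1_run(require_opt(opts, "table"))
  x_values <- as.integer(strsplit(opt_or(opts, "x", "1,3,5"), ",")[[1]])
  runs <- unlist(unname(loaded$runs), recursive = FALSE)
  report <- evaluate_runs(runs, loaded$qrels, x_values = x_values)
  out <- require_opt(opts, "out")
  write_eval_report(report, out)
  write_provenance(out, "s1-eval", opts)
  message("s1-eval: ", nrow(report$aggregate), " measure(s), ",
          length(loaded$qrels$topics), " topics")
}
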
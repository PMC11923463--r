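#' Pipeline configuration
#'
#' Bundles every stage's inputs, thresholds and seed. Inputs may be given
#' as file paths (JSONL/CSV) or as in-memory objects; referenced paths are
#' checked at validation time.
#'
#' @param corpus Path to a JSONL/CSV corpus or a `tweet_corpus` data frame.
#' @param lexicon Path to a lexicon CSV or a lexicon data frame (see
#'   [lexicon()]); its `atc` column feeds the ATC annotation.
#' @param out_dir Output directory (created if missing).
#' @param window A [study_window()].
#' @param allowlist Handles preserved by user masking.
#' @param min_drug,min_symptom Strict mention-count thresholds (defaults
#'   1000 and 250).
#' @param tau_dd,tau_ds Cosine thresholds for the drug-drug (0.005) and
#'   drug-symptom (0.05) networks.
#' @param k_grid Candidate topic counts; a single value skips selection.
#' @param lda_alpha Document-topic concentration (`NULL` = 50/K).
#' @param lda_beta Topic-word concentration.
#' @param lda_iters Gibbs sweeps.
#' @param scorer `"baseline"` or a function `(inputs) -> labels`.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, lexicon, out_dir = tempfile("drugpulse_"),
                            window = study_window(), allowlist = character(),
                            min_drug = 1000, min_symptom = 250,
                            tau_dd = 0.005, tau_ds = 0.05,
                            k_grid = 5L, lda_alpha = NULL, lda_beta = 0.01,
                            lda_iters = 200L, scorer = "baseline", seed = 1L) {
  stopifnot(min_drug >= 0, min_symptom >= 0,
            tau_dd >= 0, tau_dd < 1, tau_ds >= 0, tau_ds < 1,
            length(k_grid) >= 1)
  for (p in list(corpus, lexicon)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("input path missing: ", p, call. = FALSE)
    }
  }
  structure(list(corpus = corpus, lexicon = lexicon, out_dir = out_dir,
                 window = window, allowlist = allowlist,
                 min_drug = min_drug, min_symptom = min_symptom,
                 tau_dd = tau_dd, tau_ds = tau_ds, k_grid = as.integer(k_grid),
                 lda_alpha = lda_alpha, lda_beta = lda_beta,
                 lda_iters = as.integer(lda_iters), scorer = scorer,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields map 1:1 onto [pipeline_config()] arguments; `window` may
#' be given as `"YYYY-MM-DD:YYYY-MM-DD"`.
#'
#' @param path Config file (`.yaml`/`.yml` needs the yaml package,
#'   anything else is parsed as JSON).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$window) && is.character(raw$window)) {
    parts <- strsplit(raw$window, ":", fixed = TRUE)[[1]]
    raw$window <- study_window(parts[1], parts[2])
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess (URL filtering, user masking) -> entity extraction
#' and normalization -> frequency thresholding -> targeted sentiment ->
#' weekly trends -> topic modeling -> co-occurrence networks, each stage
#' feeding the next, and writes every artifact plus a deterministic JSON
#' run report under `config$out_dir`. Two runs with the same config and
#' seed produce byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  # -- preprocess ------------------------------------------------------
  corpus <- if (is.character(config$corpus)) read_corpus(config$corpus) else config$corpus
  report$read <- nrow(corpus)
  report$skipped_malformed <- as.integer(attr(corpus, "n_skipped") %||% 0L)
  if (report$read == 0L) {
    report$halted_at <- "preprocess"
    report$url_removed <- 0L
    report$kept <- 0L
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  fu <- filter_urls(corpus)
  kept <- fu$kept
  kept$text <- mask_users(kept$text, config$allowlist)
  report$url_removed <- fu$n_removed
  report$kept <- nrow(kept)
  write_corpus(kept, file.path(config$out_dir, "kept.jsonl"))

  # -- extract ---------------------------------------------------------
  lex <- if (is.character(config$lexicon)) read_lexicon(config$lexicon) else
    validate_lexicon(config$lexicon)
  matcher <- build_matcher(lex)
  mentions <- extract_mentions(kept, matcher)
  report$mentions <- nrow(mentions)
  counts <- table(mentions$canonical)
  mention_counts <- stats::setNames(as.integer(counts), names(counts))
  classes <- stats::setNames(lex$class, lex$canonical)[names(mention_counts)]
  retained <- frequency_filter(mention_counts, classes,
                               config$min_drug, config$min_symptom)
  report$distinct_canonicals <- length(mention_counts)
  report$retained_entities <- length(retained)
  utils::write.csv(mentions, file.path(config$out_dir, "mentions.csv"),
                   row.names = FALSE)

  # -- sentiment -------------------------------------------------------
  scorer_fn <- if (is.function(config$scorer)) config$scorer else baseline_scorer
  scorer_id <- if (is.function(config$scorer)) "custom" else config$scorer
  sc <- score_mentions(mentions, kept, scorer_fn, scorer_id)
  report$scored <- nrow(sc$scored)
  report$abstained <- sc$n_abstained
  utils::write.csv(sc$scored, file.path(config$out_dir, "scored.csv"),
                   row.names = FALSE)

  # -- trends ----------------------------------------------------------
  drug_counts <- mention_counts[classes[names(mention_counts)] == "drug"]
  top5 <- top_k_concepts(mention_counts, k = 5L, classes = classes, class = "drug")
  report$top_drugs <- as.list(top5)
  for (d in top5) {
    ser <- mention_series(mentions, kept, d, config$window)
    utils::write.csv(ser, file.path(config$out_dir, paste0("trend_", gsub("\\W", "_", d), ".csv")),
                     row.names = FALSE)
  }
  dist <- sentiment_distribution(sc$scored, intersect(top5, sc$scored$canonical))
  utils::write.csv(dist, file.path(config$out_dir, "sentiment_distribution.csv"),
                   row.names = FALSE)

  # -- topics ----------------------------------------------------------
  drug_tweets <- kept[kept$tweet_id %in% mentions$tweet_id[mentions$class == "drug"], ,
                      drop = FALSE]
  report$drug_tweets <- nrow(drug_tweets)
  if (nrow(drug_tweets) >= 10L) {
    tok <- preprocess_for_lda(drug_tweets$text, doc_ids = drug_tweets$tweet_id,
                              bigram_min_count = max(5L, nrow(drug_tweets) %/% 200L))
    if (length(config$k_grid) > 1L) {
      sel <- select_k(tok, config$k_grid, alpha = config$lda_alpha,
                      beta = config$lda_beta, n_iters = config$lda_iters,
                      seeds = config$seed + 0:2)
      k_star <- sel$k_star
      utils::write.csv(sel$diagnostics, file.path(config$out_dir, "k_selection.csv"),
                       row.names = FALSE)
    } else {
      k_star <- config$k_grid
    }
    a <- if (is.null(config$lda_alpha)) 50 / k_star else config$lda_alpha
    state <- fit_lda_gibbs(tok, K = k_star, alpha = a, beta = config$lda_beta,
                           n_iters = config$lda_iters, seed = config$seed)
    report$k_star <- k_star
    utils::write.csv(topic_summaries(state), file.path(config$out_dir, "topics.csv"),
                     row.names = FALSE)
    shares <- lapply(stats::setNames(top5, top5), function(d) {
      ids <- unique(mentions$tweet_id[mentions$canonical == d])
      idx <- which(state$doc_ids %in% ids)
      if (!length(idx)) return(NULL)
      as.list(topic_shares(state, idx))
    })
    report$topic_shares_top5 <- shares[!vapply(shares, is.null, TRUE)]
  } else {
    report$k_star <- NA
  }

  # -- networks --------------------------------------------------------
  atc_map <- stats::setNames(lex$atc, lex$canonical)
  cls_all <- stats::setNames(lex$class, lex$canonical)
  ret_drugs <- retained[cls_all[retained] == "drug"]
  ret_sympt <- retained[cls_all[retained] == "symptom"]
  all_ids <- kept$tweet_id
  if (length(ret_drugs) >= 2L && any(mentions$canonical %in% ret_drugs)) {
    dm <- build_incidence(mentions, ret_drugs, all_ids)
    dd <- build_network(dm, tau = config$tau_dd, classes = cls_all)
    part <- if (nrow(dd$nodes)) louvain(dd, seed = config$seed) else NULL
    dd <- annotate_atc(dd, atc_map)
    export_network(dd, file.path(config$out_dir, "drug_drug.gexf"),
                   membership = if (is.null(part)) NULL else part$membership)
    report$dd_nodes <- nrow(dd$nodes)
    report$dd_edges <- nrow(dd$edges)
    report$dd_modularity <- if (is.null(part)) NA else part$modularity
    report$dd_communities <- if (is.null(part)) NA else length(unique(part$membership))
  } else {
    report$dd_nodes <- 0L
    report$dd_edges <- 0L
  }
  if (length(ret_drugs) >= 1L && length(ret_sympt) >= 1L &&
      any(mentions$canonical %in% ret_drugs) && any(mentions$canonical %in% ret_sympt)) {
    dm <- build_incidence(mentions, ret_drugs, all_ids)
    sm <- build_incidence(mentions, ret_sympt, all_ids)
    ds <- drug_symptom_network(dm, sm, tau = config$tau_ds)
    export_network(ds, file.path(config$out_dir, "drug_symptom.gexf"))
    report$ds_nodes <- nrow(ds$nodes)
    report$ds_edges <- nrow(ds$edges)
  } else {
    report$ds_nodes <- 0L
    report$ds_edges <- 0L
  }

  write_report(report, config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir) {
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
}
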
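#' @useDynLib drugpulse, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# compact English stopword list; enough for token-bag tweets
default_stopwords <- function() {
  c("a", "about", "after", "again", "all", "also", "am", "an", "and", "any",
    "are", "as", "at", "be", "because", "been", "before", "being", "but",
    "by", "can", "could", "did", "do", "does", "doing", "down", "during",
    "each", "few", "for", "from", "further", "had", "has", "have", "having",
    "he", "her", "here", "hers", "him", "his", "how", "i", "if", "in",
    "into", "is", "it", "its", "just", "me", "more", "most", "my", "no",
    "nor", "not", "now", "of", "off", "on", "once", "only", "or", "other",
    "our", "out", "over", "own", "re", "s", "same", "she", "should", "so",
    "some", "such", "t", "than", "that", "the", "their", "them", "then",
    "there", "these", "they", "this", "those", "through", "to", "too",
    "under", "until", "up", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with", "you",
    "your")
}

#' Tokenize texts for topic modeling
#'
#' Lowercases, tokenizes on non-word characters, removes stopwords and
#' short tokens, then merges frequent collocations into single bigram
#' tokens (`wash hand` -> `wash_hand`) when the pair occurs at least
#' `bigram_min_count` times with normalized pointwise mutual information at
#' least `bigram_threshold`. Deterministic. Documents left empty are
#' dropped with a warning; an entirely empty corpus is an error.
#'
#' @param texts Character vector of documents.
#' @param stopwords Character vector of tokens to remove.
#' @param min_token_len Minimum token length kept.
#' @param bigram_min_count Minimum adjacent-pair count for merging.
#' @param bigram_threshold Minimum NPMI for merging (in `[-1, 1]`).
#' @param doc_ids Optional ids carried through (default positional).
#' @return A `tokenized_corpus`: list with `documents` (integer token-id
#'   vectors, 1-based), `vocabulary` (character), `bigrams` (merged pair
#'   tokens) and `doc_ids`.
#' @export
preprocess_for_lda <- function(texts, stopwords = default_stopwords(),
                               min_token_len = 3L, bigram_min_count = 20L,
                               bigram_threshold = 0.3, doc_ids = NULL) {
  if (!length(texts)) stop("preprocess_for_lda: no documents", call. = FALSE)
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(texts))
  toks <- strsplit(tolower(texts), "[^\\p{L}\\p{N}_]+", perl = TRUE)
  toks <- lapply(toks, function(t) {
    t <- t[nzchar(t)]
    t[!(t %in% stopwords) & nchar(t) >= min_token_len]
  })

  # collocation merging on adjacent pairs
  pairs <- unlist(lapply(toks, function(t) {
    if (length(t) < 2L) return(character())
    paste(t[-length(t)], t[-1L], sep = " ")
  }))
  merged <- character()
  if (length(pairs)) {
    ptab <- table(pairs)
    ptab <- ptab[ptab >= bigram_min_count]
    if (length(ptab)) {
      utab <- table(unlist(toks))
      n_tok <- sum(utab)
      n_pair <- max(1L, length(pairs))
      parts <- strsplit(names(ptab), " ", fixed = TRUE)
      npmi <- vapply(seq_along(ptab), function(i) {
        pxy <- as.numeric(ptab[i]) / n_pair
        px <- as.numeric(utab[parts[[i]][1]]) / n_tok
        py <- as.numeric(utab[parts[[i]][2]]) / n_tok
        log(pxy / (px * py)) / (-log(pxy))
      }, 0)
      merged <- names(ptab)[npmi >= bigram_threshold]
    }
  }
  if (length(merged)) {
    mset <- merged
    toks <- lapply(toks, function(t) {
      if (length(t) < 2L) return(t)
      out <- character(length(t))
      n_out <- 0L
      i <- 1L
      while (i <= length(t)) {
        if (i < length(t) && paste(t[i], t[i + 1L], sep = " ") %in% mset) {
          n_out <- n_out + 1L
          out[n_out] <- paste(t[i], t[i + 1L], sep = "_")
          i <- i + 2L
        } else {
          n_out <- n_out + 1L
          out[n_out] <- t[i]
          i <- i + 1L
        }
      }
      out[seq_len(n_out)]
    })
  }

  keep <- lengths(toks) > 0L
  if (!any(keep)) stop("preprocess_for_lda: all documents empty after filtering",
                       call. = FALSE)
  if (any(!keep)) warning(sum(!keep), " empty document(s) dropped")
  toks <- toks[keep]
  vocab <- sort(unique(unlist(toks)))
  docs <- lapply(toks, function(t) match(t, vocab))
  structure(list(documents = docs, vocabulary = vocab,
                 bigrams = sub(" ", "_", merged, fixed = TRUE),
                 doc_ids = doc_ids[keep]),
            class = "tokenized_corpus")
}

#' Build a tokenized corpus from pre-tokenized documents
#'
#' Bypass for documents that are already token lists (e.g. the synthetic
#' generator's token bags).
#' @param token_lists List of character vectors.
#' @param doc_ids Optional ids.
#' @return A `tokenized_corpus`.
#' @export
tokenized_corpus <- function(token_lists, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(token_lists))
  keep <- lengths(token_lists) > 0L
  token_lists <- token_lists[keep]
  if (!length(token_lists)) stop("tokenized_corpus: no non-empty documents", call. = FALSE)
  vocab <- sort(unique(unlist(token_lists)))
  structure(list(documents = lapply(token_lists, function(t) match(t, vocab)),
                 vocabulary = vocab, bigrams = character(), doc_ids = doc_ids[keep]),
            class = "tokenized_corpus")
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Sweeps every token, resampling its topic from the collapsed conditional
#' `p(z = k) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta)` with the
#' current token excluded from all counts. Deterministic given `seed`; the
#' joint log-likelihood is tracked per sweep.
#'
#' @param corpus A `tokenized_corpus`.
#' @param K Number of topics (>= 1, at most the total token count).
#' @param alpha Document-topic concentration; default `50 / K`.
#' @param beta Topic-word concentration; default 0.01.
#' @param n_iters Gibbs sweeps; default 500.
#' @param seed Integer seed.
#' @return An `lda_state`: counts `n_dk`, `n_kw`, `n_k`, assignments `z`,
#'   hyperparameters, `loglik` trace, `vocabulary`, `doc_ids`.
#' @export
fit_lda_gibbs <- function(corpus, K, alpha = 50 / K, beta = 0.01,
                          n_iters = 500L, seed = 1L) {
  stopifnot(inherits(corpus, "tokenized_corpus"), K >= 1, alpha > 0, beta > 0,
            n_iters >= 1)
  n_tokens <- sum(lengths(corpus$documents))
  if (K > n_tokens) stop("K exceeds the total token count", call. = FALSE)
  docs0 <- lapply(corpus$documents, function(d) as.integer(d - 1L))
  V <- length(corpus$vocabulary)
  fit <- with_seed(seed, gibbs_fit_cpp(docs0, as.integer(K), as.integer(V),
                                       alpha, beta, as.integer(n_iters)))
  state <- list(K = as.integer(K), alpha = alpha, beta = beta,
                n_dk = fit$n_dk, n_kw = fit$n_kw, n_k = fit$n_k,
                z = fit$z, loglik = fit$loglik, seed = as.integer(seed),
                iterations = as.integer(n_iters),
                vocabulary = corpus$vocabulary, doc_ids = corpus$doc_ids)
  class(state) <- "lda_state"
  check_lda_state(state, corpus)
  state
}

check_lda_state <- function(state, corpus) {
  dl <- lengths(corpus$documents)
  stopifnot(all(rowSums(state$n_dk) == dl),
            all(rowSums(state$n_kw) == state$n_k),
            all(colSums(state$n_dk) == state$n_k),
            all(state$n_dk >= 0), all(state$n_kw >= 0))
  invisible(TRUE)
}

#' Smoothed topic-word distributions
#' @param state An `lda_state`.
#' @return K x V matrix; rows sum to 1.
#' @export
phi_hat <- function(state) {
  V <- ncol(state$n_kw)
  (state$n_kw + state$beta) / (state$n_k + V * state$beta)
}

#' Smoothed document-topic distributions
#' @param state An `lda_state`.
#' @return D x K matrix; rows sum to 1.
#' @export
theta_hat <- function(state) {
  dl <- rowSums(state$n_dk)
  (state$n_dk + state$alpha) / (dl + state$K * state$alpha)
}

#' Held-out perplexity by fold-in
#'
#' Freezes the fitted topic-word distributions, samples document-topic
#' mixtures for the held-out documents by Gibbs fold-in, and returns
#' `exp(-mean log p(w))` with `p(w | d) = sum_k theta_dk phi_kw`. Held-out
#' tokens outside the training vocabulary are dropped and counted. Lower is
#' better; a uniform topic-word model over V words scores exactly V.
#'
#' @param state An `lda_state`.
#' @param heldout A `tokenized_corpus` (its vocabulary is matched to the
#'   training vocabulary by token string).
#' @param foldin_iters Gibbs sweeps for the fold-in (default 100).
#' @param seed Seed for the fold-in sampling.
#' @return Perplexity (scalar), with attribute `n_oov`.
#' @export
perplexity <- function(state, heldout, foldin_iters = 100L, seed = 1L) {
  stopifnot(inherits(heldout, "tokenized_corpus"))
  map <- match(heldout$vocabulary, state$vocabulary)
  docs <- lapply(heldout$documents, function(d) {
    m <- map[d]
    as.integer(m[!is.na(m)] - 1L)
  })
  n_oov <- sum(lengths(heldout$documents)) - sum(lengths(docs))
  docs <- docs[lengths(docs) > 0L]
  if (!length(docs)) stop("perplexity: no held-out tokens in vocabulary", call. = FALSE)
  phi <- phi_hat(state)
  theta <- with_seed(seed, gibbs_foldin_cpp(docs, phi, state$alpha,
                                            as.integer(foldin_iters)))
  ll <- 0
  n_tok <- 0L
  for (d in seq_along(docs)) {
    pw <- as.numeric(theta[d, , drop = FALSE] %*% phi[, docs[[d]] + 1L, drop = FALSE])
    ll <- ll + sum(log(pw))
    n_tok <- n_tok + length(docs[[d]])
  }
  out <- exp(-ll / n_tok)
  attr(out, "n_oov") <- n_oov
  out
}

#' UMass topic coherence
#'
#' For each topic's `topN` most probable words (descending), sums
#' `log((D(w_i, w_j) + 1) / D(w_j))` over ordered pairs `i < j`, where `D`
#' counts documents containing the word(s). Higher (closer to 0) is more
#' coherent. Pairs whose conditioning word never occurs are skipped.
#'
#' @param state An `lda_state`.
#' @param corpus The `tokenized_corpus` supplying document co-occurrence
#'   counts (normally the training corpus).
#' @param topN Words per topic (default 20, capped at V).
#' @return Numeric vector of per-topic coherence scores.
#' @export
coherence_umass <- function(state, corpus, topN = 20L) {
  V <- length(state$vocabulary)
  topN <- min(topN, V)
  phi <- phi_hat(state)
  uniq <- lapply(corpus$documents, unique)
  dfreq <- tabulate(unlist(uniq), nbins = V)
  vapply(seq_len(state$K), function(k) {
    top <- order(-phi[k, ], seq_len(V))[seq_len(topN)]
    indoc <- lapply(uniq, function(u) top[top %in% u])
    score <- 0
    for (i in seq_len(topN - 1L)) {
      for (j in seq(i + 1L, topN)) {
        wi <- top[i]; wj <- top[j]
        if (dfreq[wj] == 0L) next
        co <- sum(vapply(indoc, function(u) (wi %in% u) && (wj %in% u), TRUE))
        score <- score + log((co + 1) / dfreq[wj])
      }
    }
    score
  }, 0)
}

#' Select the number of topics on a perplexity/coherence grid
#'
#' For each K and seed, splits the corpus into train/held-out, fits by
#' collapsed Gibbs, and records held-out perplexity and mean UMass
#' coherence. The chosen K* is the grid value with the highest mean
#' coherence among those whose mean perplexity is within
#' `perplexity_tol` (relative) of the grid minimum — low perplexity and
#' high coherence jointly, with the full table returned for override.
#'
#' @param corpus A `tokenized_corpus`.
#' @param k_grid Integer vector of candidate K.
#' @param alpha Per-K document-topic concentration; `NULL` means `50 / K`.
#' @param beta Topic-word concentration.
#' @param n_iters Gibbs sweeps per fit.
#' @param seeds Integer vector of seeds (one fit per (K, seed)).
#' @param holdout_fraction Fraction of documents held out.
#' @param perplexity_tol Relative tolerance band above the minimum mean
#'   perplexity within which coherence decides.
#' @return List with `k_star` and `diagnostics` (one row per (K, seed):
#'   perplexity, mean coherence).
#' @export
select_k <- function(corpus, k_grid, alpha = NULL, beta = 0.01, n_iters = 200L,
                     seeds = 1:5, holdout_fraction = 0.1, perplexity_tol = 0.1) {
  stopifnot(length(k_grid) >= 1)
  D <- length(corpus$documents)
  rows <- list()
  for (s in seeds) {
    idx <- with_seed(s, sample.int(D))
    n_hold <- max(1L, floor(holdout_fraction * D))
    hold <- sort(idx[seq_len(n_hold)])
    train <- sort(idx[-seq_len(n_hold)])
    sub <- function(i) {
      structure(list(documents = corpus$documents[i], vocabulary = corpus$vocabulary,
                     bigrams = corpus$bigrams, doc_ids = corpus$doc_ids[i]),
                class = "tokenized_corpus")
    }
    tr <- sub(train)
    ho <- sub(hold)
    for (K in k_grid) {
      a <- if (is.null(alpha)) 50 / K else alpha
      st <- fit_lda_gibbs(tr, K = K, alpha = a, beta = beta,
                          n_iters = n_iters, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, seed = s,
        perplexity = as.numeric(perplexity(st, ho, seed = s)),
        coherence = mean(coherence_umass(st, tr)))
    }
  }
  diag <- do.call(rbind, rows)
  mper <- tapply(diag$perplexity, diag$K, mean)
  mcoh <- tapply(diag$coherence, diag$K, mean)
  ok <- mper <= min(mper) * (1 + perplexity_tol)
  cand <- names(mper)[ok]
  k_star <- as.integer(cand[which.max(mcoh[cand])])
  list(k_star = k_star, diagnostics = diag)
}

#' Top keywords per topic
#' @param state An `lda_state`.
#' @param topN Words per topic.
#' @return Data frame `topic, rank, token, probability`.
#' @export
topic_summaries <- function(state, topN = 20L) {
  phi <- phi_hat(state)
  V <- ncol(phi)
  topN <- min(topN, V)
  out <- lapply(seq_len(state$K), function(k) {
    ord <- order(-phi[k, ], seq_len(V))[seq_len(topN)]
    data.frame(topic = k, rank = seq_len(topN), token = state$vocabulary[ord],
               probability = phi[k, ord], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dominant topic per document
#'
#' `argmax theta_d`, ties broken by the lowest topic id.
#' @param state An `lda_state`.
#' @param docs Document indices (default all).
#' @return Integer vector of topic ids.
#' @export
dominant_topic <- function(state, docs = seq_len(nrow(state$n_dk))) {
  th <- theta_hat(state)[docs, , drop = FALSE]
  max.col(th, ties.method = "first")
}

#' Topic shares over a document subset
#'
#' Fraction of documents in `docs` whose dominant topic is each topic;
#' shares sum to 1.
#' @param state An `lda_state`.
#' @param docs Document indices.
#' @return Named numeric vector of length K.
#' @export
topic_shares <- function(state, docs = seq_len(nrow(state$n_dk))) {
  if (!length(docs)) stop("topic_shares: empty document subset", call. = FALSE)
  dt <- dominant_topic(state, docs)
  stats::setNames(as.numeric(table(factor(dt, levels = seq_len(state$K)))) / length(docs),
                  paste0("topic", seq_len(state$K)))
}
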
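#' Declare an entity for the synthetic generator
#'
#' @param canonical Canonical concept name.
#' @param variants Character vector of surface forms (colloquial spellings,
#'   abbreviations). The canonical itself is always included.
#' @param class `"drug"` or `"symptom"`.
#' @param base_rate Marginal probability that a tweet mentions the entity.
#' @param atc Optional ATC level-1 letter (A-V) for drugs.
#' @return A list usable in `generator_config(entity_lexicon = ...)`.
#' @export
entity_spec <- function(canonical, variants = character(), class = c("drug", "symptom"),
                        base_rate = 0.02, atc = NA_character_) {
  class <- match.arg(class)
  stopifnot(nzchar(canonical), base_rate >= 0, base_rate <= 1)
  list(canonical = canonical,
       variants = unique(c(canonical, variants)),
       class = class, base_rate = base_rate, atc = atc)
}

#' A small default entity lexicon for simulation
#'
#' Mirrors the kind of concepts a pandemic-era drug-discourse corpus
#' contains: repurposed drugs with colloquial abbreviations plus common
#' symptoms. Rates are per-tweet marginal mention probabilities.
#' @return List of [entity_spec()] entries.
#' @export
default_sim_entities <- function() {
  list(
    entity_spec("ivermectin", c("ivm"), "drug", 0.030, "P"),
    entity_spec("hydroxychloroquine", c("hcq", "plaquenil"), "drug", 0.028, "P"),
    entity_spec("remdesivir", character(), "drug", 0.015, "J"),
    entity_spec("zinc", character(), "drug", 0.020, "A"),
    entity_spec("vitamin d", c("vit d"), "drug", 0.018, "A"),
    entity_spec("azithromycin", c("zpack"), "drug", 0.012, "J"),
    entity_spec("fever", character(), "symptom", 0.025),
    entity_spec("cough", character(), "symptom", 0.020),
    entity_spec("headache", character(), "symptom", 0.015),
    entity_spec("nausea", character(), "symptom", 0.010)
  )
}

# Cue tokens the generator plants next to a mention so the deterministic
# baseline scorer can recover the latent sentiment in closed loop.
cue_tokens <- c(positive = "superb", negative = "dreadful")

sentiment_levels <- c("positive", "neutral", "negative")

#' Configuration of the synthetic tweet-corpus generator
#'
#' The generator plants (i) topic structure: each document's tokens are
#' drawn from a latent Dirichlet allocation model with `n_topics` topics,
#' document-topic concentration `alpha` and topic-word concentration
#' `beta`; (ii) entity mentions: each entity appears with its marginal
#' `base_rate`, and entities sharing a community block co-occur with joint
#' probability `rate_i * rate_j * boost`; (iii) sentiment: tweets with
#' mentions carry one latent 3-class label, drawn from the per-entity
#' profile of a uniformly chosen anchor mention, and emitted as a
#' deterministic valence cue token adjacent to each mention; (iv) URLs and
#' weekly volume: tweets carry URLs with probability `url_fraction` and
#' timestamps follow `weekly_shape` over the study window.
#'
#' @param n_tweets Number of tweets to emit.
#' @param vocab_size Background vocabulary size V.
#' @param n_topics Number of planted topics K.
#' @param alpha,beta Dirichlet concentrations for document-topic and
#'   topic-word distributions.
#' @param doc_length Tokens per tweet (before the optional handle prefix).
#' @param entity_lexicon List of [entity_spec()] entries; may be empty.
#' @param community_blocks List of `list(members = <canonicals>, boost = b)`
#'   with `b >= 1`; pairs inside a block co-occur with jointly boosted
#'   probability. Encodes the symmetric pairwise boost matrix blockwise.
#' @param sentiment_profile Named list canonical -> probability vector over
#'   (positive, neutral, negative). Entities not named get `default_profile`.
#' @param default_profile Fallback sentiment profile.
#' @param sentiment_switch Optional `list(week = w, profile = <named list>)`:
#'   from week `w` on, the switched profiles replace the originals
#'   (time-varying sentiment).
#' @param url_fraction Probability a tweet carries a URL (and so is dropped
#'   by preprocessing). Default 0.64, matching the roughly one-third
#'   retention observed in large pandemic tweet collections.
#' @param handle_fraction Probability a tweet starts with a user handle.
#' @param weekly_shape Relative volume per week index (recycled/normalized);
#'   default uniform over the window's weeks.
#' @param window A [study_window()].
#' @param topics Optional K x V matrix of planted topic-word distributions;
#'   default drawn from Dirichlet(beta).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the config.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_tweets = 2000,
                             vocab_size = 500,
                             n_topics = 5,
                             alpha = 0.3,
                             beta = 0.01,
                             doc_length = 16,
                             entity_lexicon = default_sim_entities(),
                             community_blocks = list(),
                             sentiment_profile = list(),
                             default_profile = c(positive = 0.3, neutral = 0.5, negative = 0.2),
                             sentiment_switch = NULL,
                             url_fraction = 0.64,
                             handle_fraction = 0.3,
                             weekly_shape = NULL,
                             window = study_window(),
                             topics = NULL,
                             seed = 1L) {
  stopifnot(n_tweets >= 0, vocab_size >= 1, n_topics >= 1,
            alpha > 0, beta > 0, doc_length >= 2,
            url_fraction >= 0, url_fraction <= 1,
            handle_fraction >= 0, handle_fraction <= 1)
  canonicals <- vapply(entity_lexicon, `[[`, "", "canonical")
  if (anyDuplicated(canonicals)) stop("duplicate canonical in entity_lexicon", call. = FALSE)
  all_variants <- unlist(lapply(entity_lexicon, `[[`, "variants"))
  if (anyDuplicated(tolower(all_variants))) {
    stop("variants must be unique across entities", call. = FALSE)
  }
  rates <- vapply(entity_lexicon, `[[`, 0, "base_rate")
  names(rates) <- canonicals
  for (b in community_blocks) {
    if (is.null(b$members) || is.null(b$boost) || b$boost < 1) {
      stop("community block needs members and boost >= 1", call. = FALSE)
    }
    if (!all(b$members %in% canonicals)) {
      stop("community block member not in entity_lexicon", call. = FALSE)
    }
    if (any(rates[b$members] * b$boost > 1)) {
      stop("infeasible block: base_rate * boost > 1", call. = FALSE)
    }
  }
  memb <- unlist(lapply(community_blocks, `[[`, "members"))
  if (anyDuplicated(memb)) stop("an entity may belong to at most one block", call. = FALSE)
  check_profile <- function(p, who) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("sentiment profile for ", who, " must be 3 probabilities summing to 1",
           call. = FALSE)
    }
  }
  check_profile(default_profile, "default")
  for (nm in names(sentiment_profile)) check_profile(sentiment_profile[[nm]], nm)
  if (!is.null(sentiment_switch)) {
    for (nm in names(sentiment_switch$profile)) {
      check_profile(sentiment_switch$profile[[nm]], nm)
    }
  }
  if (is.null(weekly_shape)) weekly_shape <- rep(1, window$n_weeks)
  weekly_shape <- rep_len(weekly_shape, window$n_weeks)
  if (any(weekly_shape < 0) || sum(weekly_shape) <= 0) {
    stop("weekly_shape must be non-negative with positive sum", call. = FALSE)
  }
  if (!is.null(topics)) {
    stopifnot(is.matrix(topics), nrow(topics) == n_topics, ncol(topics) == vocab_size)
    if (any(abs(rowSums(topics) - 1) > 1e-9)) {
      stop("planted topic rows must sum to 1", call. = FALSE)
    }
  }
  # entities may occupy at most every other token slot (cue slot follows)
  if (length(entity_lexicon) > 0 && floor(doc_length / 2) < 1) {
    stop("doc_length too small for entity injection", call. = FALSE)
  }
  structure(list(n_tweets = as.integer(n_tweets), vocab_size = as.integer(vocab_size),
                 n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
                 doc_length = as.integer(doc_length), entity_lexicon = entity_lexicon,
                 community_blocks = community_blocks,
                 sentiment_profile = sentiment_profile, default_profile = default_profile,
                 sentiment_switch = sentiment_switch, url_fraction = url_fraction,
                 handle_fraction = handle_fraction, weekly_shape = weekly_shape,
                 window = window, topics = topics, seed = as.integer(seed)),
            class = "generator_config")
}

# run expr with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

rdirichlet_rows <- function(n, alpha_vec) {
  k <- length(alpha_vec)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha_vec, each = n)), nrow = n)
  x / rowSums(x)
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' Deterministic given `config$seed`. See [generator_config()] for the
#' generative model. The emitted text of each tweet is a space-joined token
#' bag (optionally prefixed by a user handle) with entity surface forms and
#' sentiment cue tokens injected in-place, so every ground-truth mention's
#' surface occurs verbatim at its recorded character span.
#'
#' @param config A [generator_config()].
#' @return A list with:
#' \describe{
#'   \item{corpus}{`tweet_corpus` data frame (see [read_corpus()]).}
#'   \item{truth}{list with `mentions` (tweet_id, start, end, surface,
#'     canonical, class, sentiment), `tweets` (tweet_id, week, has_url,
#'     dominant_topic), `topics` (planted K x V topic-word matrix),
#'     `entity_class`, `community` (canonical -> block id, 0 = none), and
#'     the `config`.}
#' }
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_tweets
  W <- cfg$window$n_weeks
  K <- cfg$n_topics
  V <- cfg$vocab_size
  L <- cfg$doc_length
  vocab <- sprintf("w%03d", seq_len(V))
  ents <- cfg$entity_lexicon
  E <- length(ents)
  canonicals <- vapply(ents, `[[`, "", "canonical")
  classes <- vapply(ents, `[[`, "", "class")
  rates <- vapply(ents, `[[`, 0, "base_rate")

  empty_mentions <- data.frame(tweet_id = character(), start = integer(),
                               end = integer(), surface = character(),
                               canonical = character(), class = character(),
                               sentiment = character(), stringsAsFactors = FALSE)
  phi <- cfg$topics
  if (is.null(phi)) phi <- rdirichlet_rows(K, rep(cfg$beta, V))

  community <- stats::setNames(rep(0L, E), canonicals)
  for (i in seq_along(cfg$community_blocks)) {
    community[cfg$community_blocks[[i]]$members] <- i
  }

  if (n == 0L) {
    corpus <- data.frame(tweet_id = character(), user_id = character(),
                         created_at = as.POSIXct(character(), tz = "UTC"),
                         text = character(), stringsAsFactors = FALSE)
    class(corpus) <- c("tweet_corpus", "data.frame")
    truth <- list(mentions = empty_mentions,
                  tweets = data.frame(tweet_id = character(), week = integer(),
                                      has_url = logical(), dominant_topic = integer()),
                  topics = phi, entity_class = stats::setNames(classes, canonicals),
                  community = community, config = cfg)
    return(list(corpus = corpus, truth = truth))
  }

  tweet_id <- sprintf("t%08d", seq_len(n))
  user_id <- sprintf("u%06d", sample.int(max(1L, n %/% 2L), n, replace = TRUE))

  # timestamps: week by weekly_shape, then a uniform in-window day + second
  week <- sample.int(W, n, replace = TRUE, prob = cfg$weekly_shape) - 1L
  days_total <- as.numeric(cfg$window$end_date - cfg$window$week_anchor)
  day_in_week <- vapply(week, function(w) {
    avail <- min(6, days_total - w * 7)
    sample.int(avail + 1L, 1L) - 1L
  }, 0L)
  day <- cfg$window$week_anchor + week * 7L + day_in_week
  secs <- sample.int(86400L, n, replace = TRUE) - 1L
  created_at <- as.POSIXct(as.numeric(as.POSIXct(day, tz = "UTC")) + secs,
                           tz = "UTC", origin = "1970-01-01")

  # latent topics and background tokens
  theta <- rdirichlet_rows(n, rep(cfg$alpha, K))
  u <- matrix(stats::runif(n * L), nrow = n)
  zmat <- matrix(1L, nrow = n, ncol = L)
  if (K > 1) {
    cumth <- t(apply(theta, 1L, cumsum))
    for (k in seq_len(K - 1L)) zmat <- zmat + (u > cumth[, k])
  }
  wmat <- matrix(0L, nrow = n, ncol = L)
  for (k in seq_len(K)) {
    idx <- which(zmat == k)
    if (length(idx)) wmat[idx] <- sample.int(V, length(idx), replace = TRUE, prob = phi[k, ])
  }
  tok <- matrix(vocab[wmat], nrow = n, ncol = L)
  cnt <- vapply(seq_len(K), function(k) rowSums(zmat == k), numeric(n))
  if (n == 1L) cnt <- matrix(cnt, nrow = 1L)
  dominant_topic <- max.col(cnt, ties.method = "first")

  # entity presence: blockwise boosted, otherwise independent
  present <- matrix(FALSE, nrow = n, ncol = E)
  in_block <- community[canonicals] > 0L
  for (b in cfg$community_blocks) {
    active <- stats::runif(n) < 1 / b$boost
    for (m in b$members) {
      j <- match(m, canonicals)
      present[, j] <- active & (stats::runif(n) < rates[j] * b$boost)
    }
  }
  for (j in which(!in_block)) present[, j] <- stats::runif(n) < rates[j]

  # cap mentions per tweet at the number of injectable slots
  n_slots <- L %/% 2L
  odd_slots <- seq(1L, by = 2L, length.out = n_slots)

  profile_for <- function(canonical, wk) {
    prof <- NULL
    if (!is.null(cfg$sentiment_switch) && wk >= cfg$sentiment_switch$week) {
      prof <- cfg$sentiment_switch$profile[[canonical]]
    }
    if (is.null(prof)) prof <- cfg$sentiment_profile[[canonical]]
    if (is.null(prof)) prof <- cfg$default_profile
    prof
  }

  rows_with <- which(rowSums(present) > 0L)
  mention_rows <- vector("list", length(rows_with))
  for (ri in seq_along(rows_with)) {
    d <- rows_with[ri]
    js <- which(present[d, ])
    if (length(js) > n_slots) js <- js[seq_len(n_slots)]
    slots <- if (length(js) == 1L) odd_slots[sample.int(n_slots, 1L)] else
      sample(odd_slots, length(js))
    anchor <- if (length(js) == 1L) js else js[sample.int(length(js), 1L)]
    lab <- sample(sentiment_levels, 1L, prob = profile_for(canonicals[anchor], week[d]))
    surfs <- vapply(js, function(j) {
      v <- ents[[j]]$variants
      v[sample.int(length(v), 1L)]
    }, "")
    tok[d, slots] <- surfs
    if (lab != "neutral") tok[d, slots + 1L] <- cue_tokens[[lab]]
    mention_rows[[ri]] <- data.frame(row = d, slot = slots, surface = surfs,
                                     canonical = canonicals[js], class = classes[js],
                                     sentiment = lab, stringsAsFactors = FALSE)
  }

  # optional handle prefix, then assemble text and per-slot char offsets
  has_handle <- stats::runif(n) < cfg$handle_fraction
  prefix <- ifelse(has_handle, sprintf("@u%04d ", sample.int(9999L, n, replace = TRUE)), "")
  text <- do.call(paste, c(as.data.frame(tok, stringsAsFactors = FALSE), list(sep = " ")))
  text <- paste0(prefix, text)
  starts <- matrix(0L, nrow = n, ncol = L)
  starts[, 1L] <- nchar(prefix)
  if (L > 1L) {
    nch <- nchar(tok)
    for (j in 2:L) starts[, j] <- starts[, j - 1L] + nch[, j - 1L] + 1L
  }

  has_url <- stats::runif(n) < cfg$url_fraction
  n_url <- sum(has_url)
  if (n_url > 0L) {
    slug <- vapply(seq_len(n_url), function(i)
      paste(sample(c(letters, 0:9), 10L, replace = TRUE), collapse = ""), "")
    text[has_url] <- paste0(text[has_url], " https://t.co/", slug)
  }

  mentions <- if (length(mention_rows)) {
    mm <- do.call(rbind, mention_rows)
    st <- starts[cbind(mm$row, mm$slot)]
    out <- data.frame(tweet_id = tweet_id[mm$row], start = st,
                      end = st + nchar(mm$surface), surface = mm$surface,
                      canonical = mm$canonical, class = mm$class,
                      sentiment = mm$sentiment, stringsAsFactors = FALSE)
    out[order(out$tweet_id, out$start), , drop = FALSE]
  } else empty_mentions
  rownames(mentions) <- NULL

  corpus <- data.frame(tweet_id = tweet_id, user_id = user_id,
                       created_at = created_at, text = text, stringsAsFactors = FALSE)
  class(corpus) <- c("tweet_corpus", "data.frame")
  truth <- list(mentions = mentions,
                tweets = data.frame(tweet_id = tweet_id, week = week,
                                    has_url = has_url, dominant_topic = dominant_topic,
                                    stringsAsFactors = FALSE),
                topics = phi,
                entity_class = stats::setNames(classes, canonicals),
                community = community,
                config = cfg)
  list(corpus = corpus, truth = truth)
}

#' Lexicon table for a generator configuration
#'
#' Expands the config's entity specs into the surface-to-canonical lexicon
#' the extraction stage consumes, one row per variant.
#'
#' @param config A [generator_config()] (or a plain list of
#'   [entity_spec()] entries).
#' @return A validated lexicon data frame (see [lexicon()]).
#' @export
sim_lexicon <- function(config) {
  ents <- if (inherits(config, "generator_config")) config$entity_lexicon else config
  if (!length(ents)) stop("sim_lexicon: no entities", call. = FALSE)
  df <- do.call(rbind, lapply(ents, function(e) {
    data.frame(surface = e$variants, canonical = e$canonical, class = e$class,
               atc = if (is.null(e$atc)) NA_character_ else e$atc,
               stringsAsFactors = FALSE)
  }))
  validate_lexicon(df)
}

#' Summarize generator ground truth
#'
#' Counts agree exactly with the emitted corpus (they are recounted from the
#' truth tables, which the generator guarantees match the texts).
#'
#' @param truth The `truth` component of [generate_corpus()].
#' @return List of summary tables: `entity_counts` (mentions per canonical),
#'   `topic_proportions`, `sentiment_proportions` (per canonical over its
#'   mentions), `community` map and `n_tweets`.
#' @export
truth_report <- function(truth) {
  m <- truth$mentions
  canon <- names(truth$entity_class)
  entity_counts <- stats::setNames(integer(length(canon)), canon)
  if (nrow(m)) {
    tab <- table(m$canonical)
    entity_counts[names(tab)] <- as.integer(tab)
  }
  K <- nrow(truth$topics)
  tp <- stats::setNames(numeric(K), paste0("topic", seq_len(K)))
  if (nrow(truth$tweets)) {
    tt <- table(factor(truth$tweets$dominant_topic, levels = seq_len(K)))
    tp[] <- as.numeric(tt) / nrow(truth$tweets)
  }
  sp <- lapply(stats::setNames(canon, canon), function(cn) {
    sub <- m$sentiment[m$canonical == cn]
    if (!length(sub)) return(stats::setNames(rep(0, 3), sentiment_levels))
    stats::setNames(as.numeric(table(factor(sub, levels = sentiment_levels))) / length(sub),
                    sentiment_levels)
  })
  list(entity_counts = entity_counts, topic_proportions = tp,
       sentiment_proportions = sp, community = truth$community,
       n_tweets = nrow(truth$tweets))
}
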
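#' Build the targeted-sentiment scorer input string
#'
#' The contract any scorer adapter receives: the tweet text and the target
#' entity's canonical name joined by the special token `[SEP]`. An adapter
#' can recover the target as everything after the last `[SEP]`.
#'
#' @param text Tweet text.
#' @param canonical Target entity canonical name (non-empty).
#' @return `"<text> [SEP] <canonical>"`.
#' @examples
#' scorer_input("zinc helps", "zinc")  # "zinc helps [SEP] zinc"
#' @export
scorer_input <- function(text, canonical) {
  if (any(!nzchar(canonical))) stop("scorer_input: empty canonical", call. = FALSE)
  paste0(text, " [SEP] ", canonical)
}

#' Default valence lexicon for the baseline scorer
#'
#' Maps cue tokens to `"+"` or `"-"`; covers the deterministic cue tokens
#' the synthetic generator emits plus a few common valence words.
#' @return Named character vector token -> `"+"`/`"-"`.
#' @export
default_valence_lexicon <- function() {
  c(superb = "+", great = "+", safe = "+", effective = "+", love = "+",
    dreadful = "-", awful = "-", dangerous = "-", toxic = "-", hate = "-")
}

#' Deterministic cue-counting baseline sentiment scorer
#'
#' A stand-in for a model-based targeted sentiment classifier: splits the
#' scorer input at the last `[SEP]`, tokenizes the tweet part, and counts
#' positive vs negative cue tokens. Positive if positives outnumber
#' negatives, negative if the reverse, neutral on a tie (including zero
#' cues).
#'
#' @param input Scorer input string(s) from [scorer_input()].
#' @param valence Named vector token -> `"+"`/`"-"`.
#' @return Character vector in `positive`/`neutral`/`negative`.
#' @export
baseline_scorer <- function(input, valence = default_valence_lexicon()) {
  vapply(input, function(s) {
    tweet <- sub(" \\[SEP\\] [^[]*$", "", s)
    toks <- tolower(strsplit(tweet, "[^\\p{L}\\p{N}_@]+", perl = TRUE)[[1]])
    v <- valence[toks[toks %in% names(valence)]]
    npos <- sum(v == "+")
    nneg <- sum(v == "-")
    if (npos > nneg) "positive" else if (nneg > npos) "negative" else "neutral"
  }, "", USE.NAMES = FALSE)
}

#' Score mentions with a pluggable sentiment scorer
#'
#' Joins mentions to their tweets, builds the `[SEP]` input for each
#' (tweet, entity) pair and applies the scorer. Mentions the scorer
#' abstains on (returns `NA`) are dropped from the scored set and counted.
#'
#' @param mentions Mention data frame (see [extract_mentions()]).
#' @param corpus `tweet_corpus` the mentions came from.
#' @param scorer Function `(inputs) -> labels`; default [baseline_scorer()].
#' @param scorer_id Identifier recorded on the output.
#' @return List with `scored` (mentions + `sentiment`, `scorer_id`) and
#'   `n_abstained`.
#' @export
score_mentions <- function(mentions, corpus, scorer = baseline_scorer,
                           scorer_id = "baseline") {
  txt <- corpus$text[match(mentions$tweet_id, corpus$tweet_id)]
  if (any(is.na(txt))) stop("score_mentions: mention without matching tweet", call. = FALSE)
  if (nrow(mentions) == 0L) {
    scored <- mentions
    scored$sentiment <- character()
    scored$scorer_id <- character()
    return(list(scored = scored, n_abstained = 0L))
  }
  lab <- scorer(scorer_input(txt, mentions$canonical))
  ok <- !is.na(lab)
  bad <- lab[ok][!lab[ok] %in% sentiment_levels]
  if (length(bad)) stop("scorer returned invalid label: ", bad[1], call. = FALSE)
  scored <- mentions[ok, , drop = FALSE]
  scored$sentiment <- lab[ok]
  scored$scorer_id <- scorer_id
  rownames(scored) <- NULL
  list(scored = scored, n_abstained = sum(!ok))
}

#' Per-entity sentiment distribution
#'
#' Proportions of positive/neutral/negative over all scored mentions of
#' each canonical; the denominator is the mentions with any sentiment
#' (neutral included). Canonicals with zero scored mentions are omitted
#' with a warning.
#'
#' @param scored Scored mention data frame.
#' @param canonicals Which entities to report; default all present.
#' @return Data frame `canonical, n, p_positive, p_neutral, p_negative`.
#' @export
sentiment_distribution <- function(scored, canonicals = NULL) {
  if (is.null(canonicals)) canonicals <- sort(unique(scored$canonical))
  miss <- setdiff(canonicals, scored$canonical)
  if (length(miss)) {
    warning("no scored mentions for: ", paste(miss, collapse = ", "))
    canonicals <- setdiff(canonicals, miss)
  }
  rows <- lapply(canonicals, function(cn) {
    s <- scored$sentiment[scored$canonical == cn]
    p <- as.numeric(table(factor(s, levels = sentiment_levels))) / length(s)
    data.frame(canonical = cn, n = length(s), p_positive = p[1],
               p_neutral = p[2], p_negative = p[3], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(canonical = character(), n = integer(), p_positive = numeric(),
               p_neutral = numeric(), p_negative = numeric())
  rownames(out) <- NULL
  out
}

weekly_grid <- function(window) {
  data.frame(week = 0:(window$n_weeks - 1L))
}

#' Weekly polarity ratio series for one entity
#'
#' Per week, the fraction of scored mentions of `canonical` carrying the
#' requested polarity. Weeks with no scored mentions are `NA` (missing),
#' not 0.
#'
#' @param scored Scored mention data frame.
#' @param corpus `tweet_corpus` providing timestamps.
#' @param canonical Entity to report.
#' @param polarity `"positive"` or `"negative"`.
#' @param window A [study_window()].
#' @return Data frame `week, week_start, n_scored, n_polarity, ratio`.
#' @export
weekly_polarity_ratio <- function(scored, corpus, canonical,
                                  polarity = c("positive", "negative"),
                                  window = study_window()) {
  polarity <- match.arg(polarity)
  sub <- scored[scored$canonical == canonical, , drop = FALSE]
  wk <- week_index(corpus$created_at[match(sub$tweet_id, corpus$tweet_id)], window)
  grid <- weekly_grid(window)
  den <- tabulate(wk + 1L, nbins = window$n_weeks)
  num <- tabulate(wk[sub$sentiment == polarity] + 1L, nbins = window$n_weeks)
  grid$week_start <- window$week_anchor + grid$week * 7L
  grid$n_scored <- den
  grid$n_polarity <- num
  grid$ratio <- ifelse(den > 0L, num / den, NA_real_)
  grid
}

#' Weekly mention-count series for one entity
#'
#' Raw mention counts per week (multiplicity preserved: a tweet naming the
#' entity twice contributes two mentions). Counts over all weeks sum to the
#' entity's total mention count.
#'
#' @param mentions Mention data frame.
#' @param corpus `tweet_corpus` providing timestamps.
#' @param canonical Entity to report.
#' @param window A [study_window()].
#' @return Data frame `week, week_start, count`.
#' @export
mention_series <- function(mentions, corpus, canonical, window = study_window()) {
  sub <- mentions[mentions$canonical == canonical, , drop = FALSE]
  wk <- week_index(corpus$created_at[match(sub$tweet_id, corpus$tweet_id)], window)
  grid <- weekly_grid(window)
  grid$week_start <- window$week_anchor + grid$week * 7L
  grid$count <- tabulate(wk + 1L, nbins = window$n_weeks)
  grid
}

#' Top-k most mentioned concepts
#'
#' Descending by mention count with lexicographic tie-breaking (ties are
#' reported via a message so rankings are auditable).
#'
#' @param mention_counts Named vector canonical -> count.
#' @param k How many to return.
#' @param classes Optional named class vector to restrict by `class`.
#' @param class Restrict to one concept class if `classes` given.
#' @return Character vector of up to `k` canonicals.
#' @export
top_k_concepts <- function(mention_counts, k = 5L, classes = NULL, class = "drug") {
  if (!is.null(classes)) {
    mention_counts <- mention_counts[classes[names(mention_counts)] == class]
  }
  if (length(mention_counts) < k) {
    warning(sprintf("only %d concepts available (k=%d)", length(mention_counts), k))
  }
  ord <- order(-mention_counts, names(mention_counts))
  ranked <- names(mention_counts)[ord]
  top <- utils::head(ranked, k)
  if (length(ranked) > length(top)) {
    cutoff <- mention_counts[[top[length(top)]]]
    tied <- names(mention_counts)[mention_counts == cutoff]
    if (length(setdiff(tied, top)) > 0L) {
      message("top_k_concepts: tie at count ", cutoff, " broken lexicographically")
    }
  }
  top
}

#' Join an external weekly case-count series onto a weekly series
#'
#' Passive join on week index from a user-supplied CSV with columns
#' `week_start,count` (dates on the same weekly grid as the window).
#'
#' @param series A weekly series data frame with a `week` column.
#' @param path CSV path.
#' @param window A [study_window()].
#' @return `series` with an extra `external_count` column (`NA` where the
#'   external series has no row).
#' @export
join_case_counts <- function(series, path, window = study_window()) {
  ext <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("week_start", "count") %in% names(ext))) {
    stop("case-count CSV needs columns week_start,count", call. = FALSE)
  }
  wk <- as.integer(floor(as.numeric(as.Date(ext$week_start) - window$week_anchor) / 7))
  series$external_count <- ext$count[match(series$week, wk)]
  series
}
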
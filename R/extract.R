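#' Read a normalization lexicon from CSV
#'
#' Columns `surface,canonical,class` (header required) plus optional `atc`
#' (ATC level-1 letter). The surface-to-canonical mapping must be a
#' function and each canonical must map to exactly one concept class.
#'
#' @param path CSV path (UTF-8).
#' @return A validated lexicon data frame.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  need <- c("surface", "canonical", "class")
  if (!all(need %in% names(df))) {
    stop("lexicon CSV needs columns surface,canonical,class", call. = FALSE)
  }
  if (!"atc" %in% names(df)) df$atc <- NA_character_
  df$atc[!nzchar(trimws(ifelse(is.na(df$atc), "", df$atc)))] <- NA_character_
  validate_lexicon(df[, c("surface", "canonical", "class", "atc")])
}

#' Build a lexicon data frame in code
#'
#' @param surface,canonical,class,atc Parallel character vectors.
#' @return A validated lexicon data frame.
#' @export
lexicon <- function(surface, canonical, class, atc = NA_character_) {
  validate_lexicon(data.frame(surface = surface, canonical = canonical,
                              class = class, atc = atc, stringsAsFactors = FALSE))
}

validate_lexicon <- function(df) {
  if (any(!nzchar(trimws(df$surface)))) stop("empty surface in lexicon", call. = FALSE)
  if (!all(df$class %in% c("drug", "symptom"))) {
    stop("lexicon class must be drug or symptom", call. = FALSE)
  }
  key <- tolower(df$surface)
  dup <- duplicated(key)
  if (any(dup)) {
    # duplicates allowed only if they agree on canonical
    for (k in unique(key[dup])) {
      if (length(unique(df$canonical[key == k])) > 1L) {
        stop("surface '", k, "' maps to multiple canonicals", call. = FALSE)
      }
    }
    df <- df[!dup, , drop = FALSE]
  }
  for (cn in unique(df$canonical)) {
    if (length(unique(df$class[df$canonical == cn])) > 1L) {
      stop("canonical '", cn, "' maps to multiple classes", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Compile a lexicon into a scanning matcher
#'
#' Matching is case-insensitive with word boundaries (a surface must not be
#' flanked by word characters) and longest-match-first with left-to-right
#' tie-breaking, so nested surfaces ("vitamin" inside "vitamin d") are not
#' double counted. Multiword surfaces are supported.
#'
#' @param lex Lexicon data frame from [lexicon()] or [read_lexicon()].
#' @return An object of class `entity_matcher`.
#' @export
build_matcher <- function(lex) {
  lex <- validate_lexicon(lex)
  surfaces <- lex$surface[order(-nchar(lex$surface), tolower(lex$surface))]
  esc <- gsub("([^A-Za-z0-9_ ])", "\\\\\\1", surfaces, perl = TRUE)
  pattern <- sprintf("(?<![\\w])(%s)(?![\\w])", paste(esc, collapse = "|"))
  key <- tolower(lex$surface)
  structure(list(lexicon = lex, pattern = pattern,
                 canonical = stats::setNames(lex$canonical, key),
                 class = stats::setNames(lex$class, key)),
            class = "entity_matcher")
}

#' Extract normalized entity mentions from texts
#'
#' Runs the matcher over each text and returns one row per mention with
#' 0-based half-open character spans, the matched surface and its canonical
#' concept. Mentions are ordered by (tweet, span start); spans never
#' overlap (longest-match-first greedy scan).
#'
#' @param corpus A `tweet_corpus` data frame (or any data frame with
#'   `tweet_id` and `text`).
#' @param matcher An [build_matcher()] object.
#' @return Data frame `tweet_id, start, end, surface, canonical, class`.
#' @export
extract_mentions <- function(corpus, matcher) {
  stopifnot(inherits(matcher, "entity_matcher"))
  empty <- data.frame(tweet_id = character(), start = integer(), end = integer(),
                      surface = character(), canonical = character(),
                      class = character(), stringsAsFactors = FALSE)
  if (nrow(corpus) == 0L) return(empty)
  ms <- gregexpr(matcher$pattern, corpus$text, perl = TRUE, ignore.case = TRUE)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    m <- ms[[i]]
    if (m[1] == -1L) next
    st <- as.integer(m) - 1L           # to 0-based
    len <- attr(m, "match.length")
    surf <- substring(corpus$text[i], st + 1L, st + len)
    k <- tolower(surf)
    out[[i]] <- data.frame(tweet_id = corpus$tweet_id[i], start = st,
                           end = st + len, surface = surf,
                           canonical = unname(matcher$canonical[k]),
                           class = unname(matcher$class[k]),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize externally tagged mentions against a lexicon
#'
#' Mentions whose surface is not in the lexicon are dropped and counted as
#' unmapped (downstream stages require canonical concepts). Idempotent:
#' already-normalized mentions pass through unchanged.
#'
#' @param mentions Data frame with at least `tweet_id,start,end,surface`.
#' @param matcher An [build_matcher()] object.
#' @return List with `mentions` (normalized) and `n_unmapped`.
#' @export
normalize_mentions <- function(mentions, matcher) {
  k <- tolower(mentions$surface)
  known <- k %in% names(matcher$canonical)
  kept <- mentions[known, , drop = FALSE]
  kept$canonical <- unname(matcher$canonical[tolower(kept$surface)])
  kept$class <- unname(matcher$class[tolower(kept$surface)])
  rownames(kept) <- NULL
  list(mentions = kept, n_unmapped = sum(!known))
}

#' Extract mentions through an optional external tagger
#'
#' Hook for plugging a model-based named-entity tagger into the pipeline.
#' The tagger is a function `(corpus) -> mentions` returning raw spans and
#' surfaces; its output is passed through [normalize_mentions()] so
#' downstream stages always see canonical concepts. With no tagger
#' registered, falls back to the lexicon matcher with a notice.
#'
#' @param corpus A `tweet_corpus` data frame.
#' @param matcher An [build_matcher()] object (used for normalization and
#'   as the fallback).
#' @param tagger Optional function `(corpus) -> data.frame`.
#' @return List with `mentions` and `n_unmapped`.
#' @export
tagged_mentions <- function(corpus, matcher, tagger = NULL) {
  if (is.null(tagger)) {
    message("no external tagger registered; falling back to lexicon matcher")
    return(list(mentions = extract_mentions(corpus, matcher), n_unmapped = 0L))
  }
  raw <- tagger(corpus)
  normalize_mentions(raw, matcher)
}

#' Frequency thresholding of canonical concepts
#'
#' Drugs are retained iff mentioned strictly more than `min_drug` times and
#' symptoms strictly more than `min_symptom` times (defaults 1000 and 250).
#' A concept at exactly the threshold is excluded.
#'
#' @param mention_counts Named integer vector, canonical -> mention count.
#' @param classes Named character vector, canonical -> class.
#' @param min_drug,min_symptom Strict lower bounds.
#' @return Character vector of retained canonicals (input order).
#' @export
frequency_filter <- function(mention_counts, classes, min_drug = 1000, min_symptom = 250) {
  stopifnot(all(mention_counts >= 0))
  canon <- names(mention_counts)
  cls <- classes[canon]
  thr <- ifelse(cls == "drug", min_drug, min_symptom)
  canon[mention_counts > thr]
}

#' Yates-corrected chi-square statistic for a 2x2 table
#'
#' `sum( (max(|O - E| - 1/2, 0))^2 / E )` over the four cells, with
#' expectations from the row and column margins; 1 degree of freedom.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows = methods,
#'   columns = correct/incorrect).
#' @return List with `statistic` and `df = 1`.
#' @export
chi_square_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)), all(table >= 0))
  n <- sum(table)
  E <- outer(rowSums(table), colSums(table)) / n
  if (any(E == 0)) stop("chi_square_yates: zero expected cell", call. = FALSE)
  stat <- sum(pmax(abs(table - E) - 0.5, 0)^2 / E)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Compare two extraction methods against gold labels
#'
#' The evaluation harness behind method-accuracy comparisons: per-item
#' correctness of each method against the gold standard, a 2x2
#' method-by-correctness contingency table, and its Yates-corrected
#' chi-square statistic.
#'
#' @param pred_a,pred_b,gold Aligned label vectors of equal length.
#' @return List with `acc_a`, `acc_b`, `table` (2x2: rows methods, columns
#'   correct/incorrect) and `chisq` (from [chi_square_yates()]).
#' @export
evaluate_extraction <- function(pred_a, pred_b, gold) {
  if (length(pred_a) != length(gold) || length(pred_b) != length(gold)) {
    stop("evaluate_extraction: label vectors must be aligned", call. = FALSE)
  }
  ca <- sum(pred_a == gold)
  cb <- sum(pred_b == gold)
  n <- length(gold)
  tab <- matrix(c(ca, n - ca, cb, n - cb), nrow = 2L, byrow = TRUE,
                dimnames = list(c("method_a", "method_b"), c("correct", "incorrect")))
  list(acc_a = ca / n, acc_b = cb / n, table = tab, chisq = chi_square_yates(tab))
}

#' 2x2 accuracy table implied by two accuracy rates
#'
#' Builds the contingency table for `n` evaluated items per method at the
#' given accuracies (counts rounded to integers).
#'
#' @param acc_a,acc_b Accuracy proportions in `[0,1]`.
#' @param n Items evaluated per method.
#' @return 2x2 integer matrix (rows methods, columns correct/incorrect).
#' @export
accuracy_table <- function(acc_a, acc_b, n = 1000L) {
  ca <- round(acc_a * n)
  cb <- round(acc_b * n)
  matrix(c(ca, n - ca, cb, n - cb), nrow = 2L, byrow = TRUE,
         dimnames = list(c("method_a", "method_b"), c("correct", "incorrect")))
}
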
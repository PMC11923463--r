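#' Study window for weekly binning
#'
#' A study window is a closed calendar-date interval together with a week
#' anchor. All weekly series in the package use consecutive 7-day bins
#' counted from the anchor (not ISO weeks), so that "week 0" starts on the
#' first day of data collection.
#'
#' @param start_date,end_date `Date` (or coercible strings) bounding the
#'   window, inclusive. Defaults cover 2020-02-01 through 2022-04-30.
#' @param week_anchor `Date` the weekly grid is counted from; must not be
#'   after `start_date`. Defaults to `start_date`.
#' @return An object of class `study_window` with fields `start_date`,
#'   `end_date`, `week_anchor` and `n_weeks` (number of 7-day bins touched
#'   by the window).
#' @examples
#' w <- study_window()
#' w$n_weeks  # 118 bins: weeks 0..117
#' @export
study_window <- function(start_date = "2020-02-01", end_date = "2022-04-30",
                         week_anchor = start_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  week_anchor <- as.Date(week_anchor)
  if (is.na(start_date) || is.na(end_date) || is.na(week_anchor)) {
    stop("study_window: dates must be parseable as Date", call. = FALSE)
  }
  if (start_date > end_date) stop("study_window: start_date > end_date", call. = FALSE)
  if (week_anchor > start_date) stop("study_window: week_anchor > start_date", call. = FALSE)
  n_weeks <- as.integer(floor(as.numeric(end_date - week_anchor) / 7)) + 1L
  structure(list(start_date = start_date, end_date = end_date,
                 week_anchor = week_anchor, n_weeks = n_weeks),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("study_window: %s .. %s (anchor %s, %d weekly bins)\n",
              x$start_date, x$end_date, x$week_anchor, x$n_weeks))
  invisible(x)
}

tweet_columns <- c("tweet_id", "user_id", "created_at", "text")

#' Read a tweet corpus from JSONL or CSV
#'
#' Each record needs four fields: `tweet_id`, `user_id`, `created_at`
#' (ISO-8601 UTC timestamp) and `text`. Malformed records (missing or empty
#' fields, unparseable JSON lines or timestamps) are skipped and counted;
#' more than 50% malformed lines is treated as a format error. Duplicate
#' `tweet_id`s keep the first occurrence with a warning.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (header
#'   required). Default guesses from the file extension.
#' @return A data frame of class `tweet_corpus` with character columns
#'   `tweet_id`, `user_id`, `text` and a POSIXct (UTC) column `created_at`,
#'   plus attribute `n_skipped`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_corpus: no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    ok <- vapply(recs, function(r) {
      is.list(r) && all(tweet_columns %in% names(r)) &&
        all(vapply(r[tweet_columns], function(v)
          length(v) == 1L && !is.na(v) && nzchar(trimws(as.character(v))), TRUE))
    }, TRUE)
    n_total <- length(recs)
    df <- if (any(ok)) {
      do.call(rbind, lapply(recs[ok], function(r)
        as.data.frame(lapply(r[tweet_columns], as.character))))
    } else {
      as.data.frame(stats::setNames(rep(list(character()), 4L), tweet_columns))
    }
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
    if (!all(tweet_columns %in% names(df))) {
      stop("read_corpus: CSV must have columns ", paste(tweet_columns, collapse = ", "),
           call. = FALSE)
    }
    df <- df[, tweet_columns]
    n_total <- nrow(df)
    ok_row <- rowSums(is.na(df) | !nzchar(trimws(as.matrix(df)))) == 0L
    df <- df[ok_row, , drop = FALSE]
  }
  ts <- as.POSIXct(df$created_at, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  good_ts <- !is.na(ts)
  df <- df[good_ts, , drop = FALSE]
  ts <- ts[good_ts]
  n_skipped <- n_total - nrow(df)
  if (n_total > 0L && n_skipped / n_total > 0.5) {
    stop(sprintf("read_corpus: %d/%d records malformed (>50%%)", n_skipped, n_total),
         call. = FALSE)
  }
  dup <- duplicated(df$tweet_id)
  if (any(dup)) {
    warning(sprintf("read_corpus: %d duplicate tweet_id(s); keeping first", sum(dup)))
    df <- df[!dup, , drop = FALSE]
    ts <- ts[!dup]
  }
  out <- data.frame(tweet_id = df$tweet_id, user_id = df$user_id,
                    created_at = ts, text = df$text, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tweet_corpus", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a tweet corpus to JSONL or CSV
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f), ...)` returns
#' the same field values.
#'
#' @param corpus A `tweet_corpus` data frame.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  ts <- format(corpus$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df <- data.frame(tweet_id = corpus$tweet_id, user_id = corpus$user_id,
                   created_at = ts, text = corpus$text, stringsAsFactors = FALSE)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i)
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Default URL pattern: scheme-prefixed links and bare www.-prefixed tokens.
url_pattern_default <- "(https?://\\S+|\\bwww\\.\\S+)"

#' Remove posts that contain URLs
#'
#' Posts carrying hyperlinks are usually headlines or quotations rather than
#' first-person discourse, so they are excluded before any analysis. A post
#' is removed iff its text matches `pattern`.
#'
#' @param corpus A `tweet_corpus` data frame.
#' @param pattern Perl regex identifying a URL. The default catches
#'   `http://`/`https://` links and bare `www.`-prefixed tokens.
#' @return A list with `kept` (filtered corpus) and `n_removed`.
#' @export
filter_urls <- function(corpus, pattern = url_pattern_default) {
  has_url <- grepl(pattern, corpus$text, perl = TRUE)
  kept <- corpus[!has_url, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("tweet_corpus", "data.frame")
  list(kept = kept, n_removed = sum(has_url))
}

#' Mask user handles in text
#'
#' Every `@handle` token not on the allowlist is replaced by `@USER`;
#' allowlisted handles (public figures) are preserved verbatim. Matching of
#' allowlist entries is case-insensitive.
#'
#' @param text Character vector.
#' @param allowlist Character vector of handles (without the `@`) to keep.
#' @return Character vector with handles masked.
#' @examples
#' mask_users("@alice try zinc")                       # "@USER try zinc"
#' mask_users("@BigName said X", allowlist = "bigname") # unchanged
#' @export
mask_users <- function(text, allowlist = character()) {
  allow <- tolower(allowlist)
  vapply(text, function(t) {
    m <- gregexpr("@[A-Za-z0-9_]+", t, perl = TRUE)[[1]]
    if (m[1] == -1L) return(t)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    # replace right-to-left so earlier offsets stay valid
    for (i in rev(seq_along(starts))) {
      h <- substr(t, starts[i] + 1L, starts[i] + lens[i] - 1L)
      if (!(tolower(h) %in% allow)) {
        t <- paste0(substr(t, 1L, starts[i] - 1L), "@USER",
                    substr(t, starts[i] + lens[i], nchar(t)))
      }
    }
    t
  }, "", USE.NAMES = FALSE)
}

#' Weekly bin index of a timestamp
#'
#' `floor(days since week_anchor / 7)`: consecutive anchor-aligned 7-day
#' bins. For the default window (2020-02-01 .. 2022-04-30) indices run 0..117.
#'
#' @param timestamp POSIXct or Date vector.
#' @param window A [study_window()].
#' @return Integer vector of week indices (0-based).
#' @export
week_index <- function(timestamp, window = study_window()) {
  d <- as.Date(timestamp, tz = "UTC")
  if (any(d < window$start_date | d > window$end_date, na.rm = TRUE)) {
    stop("week_index: timestamp outside study window", call. = FALSE)
  }
  as.integer(floor(as.numeric(d - window$week_anchor) / 7))
}
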
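test_that("scorer_input follows the [SEP] contract and round-trips the entity", {
  s <- scorer_input("zinc helps", "zinc")
  expect_identical(s, "zinc helps [SEP] zinc")
  expect_identical(sub("^.* \\[SEP\\] ", "", s), "zinc")
  expect_error(scorer_input("text", ""), "empty canonical")
})

test_that("baseline scorer counts valence cues in the tweet part only", {
  v <- c(great = "+", safe = "+", awful = "-")
  expect_equal(baseline_scorer("great safe drug [SEP] zinc", v), "positive")
  expect_equal(baseline_scorer("no cues at all [SEP] zinc", v), "neutral")
  expect_equal(baseline_scorer("great but awful [SEP] zinc", v), "neutral")
  expect_equal(baseline_scorer("awful stuff [SEP] great", v), "negative")
})

test_that("baseline scorer recovers generator sentiment labels exactly", {
  cfg <- generator_config(n_tweets = 800, url_fraction = 0, seed = 23)
  sim <- generate_corpus(cfg)
  men <- extract_mentions(sim$corpus, build_matcher(sim_lexicon(cfg)))
  sc <- score_mentions(men, sim$corpus)
  expect_equal(sc$n_abstained, 0L)
  tm <- sim$truth$mentions
  mg <- merge(sc$scored, tm[, c("tweet_id", "start", "sentiment")],
              by = c("tweet_id", "start"))
  expect_equal(nrow(mg), nrow(sc$scored))
  expect_identical(mg$sentiment.x, mg$sentiment.y)
})

test_that("abstaining scorers shrink the scored set and are counted", {
  corp <- mini_corpus(c("zinc one", "zinc two"))
  men <- extract_mentions(corp, build_matcher(toy_lexicon()))
  flaky <- function(inputs) c("positive", NA)
  sc <- score_mentions(men, corp, flaky, "flaky")
  expect_equal(nrow(sc$scored), 1L)
  expect_equal(sc$n_abstained, 1L)
  bad <- function(inputs) rep("meh", length(inputs))
  expect_error(score_mentions(men, corp, bad), "invalid label")
})

test_that("sentiment_distribution proportions are exact and sum to one", {
  scored <- data.frame(canonical = rep("zinc", 3),
                       sentiment = c("positive", "neutral", "negative"))
  d <- sentiment_distribution(scored)
  expect_equal(unlist(d[, c("p_positive", "p_neutral", "p_negative")]),
               c(p_positive = 1/3, p_neutral = 1/3, p_negative = 1/3))

  allpos <- data.frame(canonical = "hcq", sentiment = rep("positive", 4))
  expect_equal(sentiment_distribution(allpos)$p_positive, 1)

  expect_warning(sentiment_distribution(scored, c("zinc", "ghost")), "ghost")

  # multinomial oracle on a planted single-drug profile
  cfg <- generator_config(n_tweets = 10000, url_fraction = 0, handle_fraction = 0,
                          entity_lexicon = list(entity_spec("zinc", class = "drug",
                                                            base_rate = 0.5)),
                          sentiment_profile = list(zinc = c(0.6, 0.3, 0.1)),
                          seed = 31)
  sim <- generate_corpus(cfg)
  men <- extract_mentions(sim$corpus, build_matcher(sim_lexicon(cfg)))
  sc <- score_mentions(men, sim$corpus)
  d <- sentiment_distribution(sc$scored)
  n <- d$n
  expect_gt(n, 4000)
  for (col in c("p_positive", "p_neutral", "p_negative")) {
    p0 <- c(p_positive = 0.6, p_neutral = 0.3, p_negative = 0.1)[[col]]
    expect_lt(abs(d[[col]] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  expect_equal(d$p_positive + d$p_neutral + d$p_negative, 1, tolerance = 1e-9)
})

test_that("weekly polarity ratios use per-week denominators with missing markers", {
  w <- study_window("2020-02-01", "2020-02-28")
  corp <- mini_corpus(rep("x", 4))
  corp$created_at <- as.POSIXct(c("2020-02-02", "2020-02-03", "2020-02-04", "2020-02-05"),
                                tz = "UTC")
  scored <- data.frame(tweet_id = corp$tweet_id, canonical = "zinc",
                       sentiment = c("positive", "positive", "negative", "neutral"))
  ser <- weekly_polarity_ratio(scored, corp, "zinc", "positive", w)
  expect_equal(ser$ratio[1], 0.5)            # 2 positive of 4 scored
  expect_true(is.na(ser$ratio[2]))           # empty week is missing, not 0
  expect_true(all(ser$n_polarity <= ser$n_scored))
  ok <- !is.na(ser$ratio)
  expect_true(all(ser$ratio[ok] >= 0 & ser$ratio[ok] <= 1))
})

test_that("a planted sentiment switch shows up as a step in the weekly ratio", {
  w <- study_window("2020-02-01", "2020-06-30")
  cfg <- generator_config(
    n_tweets = 6000, url_fraction = 0, handle_fraction = 0, window = w,
    entity_lexicon = list(entity_spec("zinc", class = "drug", base_rate = 0.8)),
    sentiment_profile = list(zinc = c(0.8, 0.1, 0.1)),
    sentiment_switch = list(week = 10, profile = list(zinc = c(0.1, 0.1, 0.8))),
    seed = 41)
  sim <- generate_corpus(cfg)
  men <- extract_mentions(sim$corpus, build_matcher(sim_lexicon(cfg)))
  sc <- score_mentions(men, sim$corpus)
  ser <- weekly_polarity_ratio(sc$scored, sim$corpus, "zinc", "positive", w)
  before <- mean(ser$ratio[ser$week < 10], na.rm = TRUE)
  after <- mean(ser$ratio[ser$week >= 10], na.rm = TRUE)
  expect_gt(before, 0.7)
  expect_lt(after, 0.2)
})

test_that("mention series conserve totals and recover the planted volume peak", {
  w <- study_window("2020-02-01", "2020-03-31")
  corp <- mini_corpus(rep("x", 5))
  corp$created_at <- rep(as.POSIXct("2020-02-03", tz = "UTC"), 5)
  men <- data.frame(tweet_id = corp$tweet_id, canonical = "zinc")
  ser <- mention_series(men, corp, "zinc", w)
  expect_equal(ser$count[1], 5L)
  expect_equal(sum(ser$count), nrow(men))

  shape <- rep(1, 118); shape[31] <- 40   # week index 30 dominates
  cfg <- generator_config(n_tweets = 50000, url_fraction = 0, weekly_shape = shape,
                          entity_lexicon = list(entity_spec("zinc", class = "drug",
                                                            base_rate = 0.3)),
                          seed = 47)
  sim <- generate_corpus(cfg)
  men <- sim$truth$mentions
  ser <- mention_series(men, sim$corpus, "zinc")
  expect_equal(ser$week[which.max(ser$count)], 30)
  expect_equal(sum(ser$count), nrow(men))
})

test_that("top_k_concepts ranks by count with lexicographic tie-breaking", {
  expect_identical(top_k_concepts(c(a = 3, b = 2, c = 1), k = 2), c("a", "b"))
  expect_message(got <- top_k_concepts(c(b = 2, a = 2), k = 1), "tie")
  expect_identical(got, "a")
  expect_warning(top_k_concepts(c(a = 1), k = 5), "only 1")

  # planted rate ordering is recovered at scale
  ents <- list(entity_spec("top", class = "drug", base_rate = 0.10),
               entity_spec("mid", class = "drug", base_rate = 0.05),
               entity_spec("low", class = "drug", base_rate = 0.02))
  cfg <- generator_config(n_tweets = 20000, entity_lexicon = ents,
                          url_fraction = 0, seed = 53)
  sim <- generate_corpus(cfg)
  counts <- table(sim$truth$mentions$canonical)
  got <- top_k_concepts(stats::setNames(as.numeric(counts), names(counts)), k = 3)
  expect_identical(got, c("top", "mid", "low"))
})
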
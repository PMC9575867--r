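small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed,
                    window = analysis_window("2020-01-01", "2020-03-31"),
                    n_leaders = 2, n_health_orgs = 2,
                    tweets_per_day = c(leader = 2, health_org = 3), ...)
}

test_that("equal seeds give byte-identical corpora; different seeds differ", {
  a <- simulate_cohort(small_cfg(seed = 5))
  b <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(a$tweets, b$tweets)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$roster, b$roster)
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$tweets, c$tweets))
})

test_that("config validation rejects bad probabilities and rates", {
  expect_error(small_cfg(sentiment_mix = c(negative = 0.5, neutral = 0.5,
                                           positive = 0.5)), "sum to 1")
  expect_error(small_cfg(mention_prob = 1.5), "mention_prob")
  expect_error(small_cfg(engagement_dispersion = 0), "dispersion")
})

test_that("mention_prob = 0 yields a keyword-free corpus; pure mixes classify purely", {
  co <- simulate_cohort(small_cfg(seed = 2, mention_prob = 0))
  hits <- mentions_community(co$tweets$text, default_community_lexicon())
  expect_false(any(hits))

  pos <- simulate_cohort(small_cfg(seed = 3,
                                   sentiment_mix = c(negative = 0, neutral = 0,
                                                     positive = 1),
                                   mention_prob = 0))
  labels <- classify_sentiment(pos$tweets$text)
  expect_true(all(labels == "positive"))
})

test_that("engagement mean matches the negative-binomial target within 3 SE", {
  cfg <- simulation_config(seed = 12,
                           window = analysis_window("2019-12-01", "2021-12-31"),
                           n_leaders = 4, n_health_orgs = 0,
                           tweets_per_day = c(leader = 4, health_org = 0),
                           engagement_mean = c(leader = 150, health_org = 30),
                           spike_schedule = data.frame(date = as.Date(character()),
                                                       multiplier = numeric()),
                           dual_handle_first_leader = FALSE)
  co <- simulate_cohort(cfg)
  total <- co$tweets$like_count + co$tweets$reply_count +
    co$tweets$retweet_count + co$tweets$quote_count
  expect_gte(length(total), 10000)
  mu <- 150; size <- cfg$engagement_dispersion
  se <- sqrt((mu + mu^2 / size) / length(total))
  expect_lt(abs(mean(total) - mu), 3 * se)
})

test_that("sentiment label frequencies converge to the configured mix", {
  cfg <- simulation_config(seed = 13,
                           window = analysis_window("2019-12-01", "2021-12-31"),
                           n_leaders = 3, n_health_orgs = 0,
                           tweets_per_day = c(leader = 5, health_org = 0),
                           mention_prob = 0, dual_handle_first_leader = FALSE)
  co <- simulate_cohort(cfg)
  labels <- classify_sentiment(co$tweets$text)
  expect_gte(length(labels), 10000)
  obs <- table(factor(labels, levels = c("negative", "neutral", "positive")))
  gof <- stats::chisq.test(obs, p = cfg$sentiment_mix[c("negative", "neutral",
                                                        "positive")])
  expect_gt(gof$p.value, 0.01)
})

test_that("spike days carry strictly higher mean engagement than neighbors", {
  cfg <- simulation_config(seed = 14,
                           window = analysis_window("2020-04-01", "2020-04-20"),
                           n_leaders = 6, n_health_orgs = 6,
                           tweets_per_day = c(leader = 40, health_org = 40),
                           spike_schedule = data.frame(date = as.Date("2020-04-10"),
                                                       multiplier = 6),
                           dual_handle_first_leader = FALSE)
  co <- simulate_cohort(cfg)
  d <- as.Date(co$tweets$created_at, tz = "UTC")
  total <- co$tweets$like_count + co$tweets$reply_count +
    co$tweets$retweet_count + co$tweets$quote_count
  spike_mean <- mean(total[d == as.Date("2020-04-10")])
  flank_mean <- mean(total[d %in% as.Date(c("2020-04-09", "2020-04-11"))])
  expect_gt(spike_mean, flank_mean)
})

test_that("planting rejects fractions not expressible at the tweet count", {
  cfg <- small_cfg()
  expect_error(plant_known_strengths(cfg, data.frame(
    n_tweets = 10, sentiment_fraction = 0.55, mention_fraction = 0)),
    "not expressible")
  expect_error(plant_known_strengths(cfg, data.frame(
    n_tweets = 12, sentiment_fraction = 0.25, mention_fraction = 0)),
    "strict majority")
  expect_error(plant_known_strengths(cfg, data.frame(
    n_tweets = 12, sentiment_fraction = 0.5, mention_fraction = 1 / 7)),
    "mention_fraction")
})

test_that("written cohorts reload identically through both dialects", {
  co <- simulate_cohort(small_cfg(seed = 9))
  for (dialect in c("flat_csv", "api_v2_jsonl")) {
    dir <- withr::local_tempdir()
    paths <- write_cohort(co, dir, dialect)
    back <- read_tweets(paths[["tweets"]], dialect)
    expect_equal(back, co$tweets)
    expect_equal(read_roster(paths[["roster"]]), co$roster)
  }
})
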
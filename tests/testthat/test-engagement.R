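test_that("user impact matches the closed form and its edge identities", {
  # listed_count = 0 -> tanh(0) = 0
  expect_equal(user_impact(500, 10, 0, 100, 365), 0)
  # follower ratio exactly 1 -> log10 = 0
  expect_equal(user_impact(100, 10, 50, 1000, 365), 0)
  # high-precision closed form: tanh saturates, value = 1 / age^2
  expect_equal(user_impact(1e6, 100, 50, 1000, 1000), tanh(5e4) / 1e6)
  expect_equal(user_impact(1e6, 100, 50, 1000, 1000), 1e-6, tolerance = 1e-12)

  expect_error(user_impact(100, 0, 5, 10, 100), "following")
  expect_error(user_impact(0, 10, 5, 10, 100), "followers")
  expect_error(user_impact(100, 10, 5, 10, 0), "age")
})

test_that("impact magnitude is bounded by 1/age^2 over random valid profiles", {
  set.seed(42)
  n <- 1000
  followers <- round(10^runif(n, 0.1, 8))
  following <- sample(1:5000, n, replace = TRUE)
  listed <- sample(0:5000, n, replace = TRUE)
  tweets <- sample(0:50000, n, replace = TRUE)
  age <- sample(1:6000, n, replace = TRUE)
  imp <- user_impact(pmax(followers, 1), following, listed, tweets, age)
  expect_true(all(abs(imp) < 1 / age^2 + 1e-15))
})

test_that("impacts min-max scale to [0,1] within group with max 1", {
  df <- tibble::tibble(user_id = c("a", "b", "c", "d", "e"),
                       group = c("leader", "leader", "leader",
                                 "health_org", "health_org"),
                       raw_impact = c(2, 1, 0, 5, 3))
  s <- scale_impacts(df)
  expect_equal(s$scaled_impact[match(c("a", "b", "c"), s$user_id)],
               c(1, 0.5, 0))
  expect_equal(s$scaled_impact[match(c("d", "e"), s$user_id)], c(1, 0))
  # degenerate: all equal -> all 1.0 (top of a group scores 1.000)
  flat <- tibble::tibble(user_id = c("x", "y"), group = "leader",
                         raw_impact = c(0.3, 0.3))
  expect_equal(scale_impacts(flat)$scaled_impact, c(1, 1))
  expect_error(scale_impacts(flat[0, ]), "empty")
})

test_that("daily average engagement divides pooled counts by 4x tweet count", {
  expect_equal(daily_avg_engagement(10, 2, 4, 0, 1), 4)
  expect_equal(daily_avg_engagement(0, 0, 0, 0, 1), 0)
  expect_equal(daily_avg_engagement(8, 4, 4, 0, 2), 2)
  expect_error(daily_avg_engagement(1, 1, 1, 1, 0), "daily_tweet_count")
  # scale equivariance: doubling every count doubles the average
  set.seed(3)
  l <- sample(0:50, 20); r <- sample(0:50, 20)
  rt <- sample(0:50, 20); q <- sample(0:50, 20); n <- sample(1:5, 20, TRUE)
  expect_equal(daily_avg_engagement(2 * l, 2 * r, 2 * rt, 2 * q, n),
               2 * daily_avg_engagement(l, r, rt, q, n))
})

test_that("smoothing chain preserves constants and removes planted spikes", {
  const <- rep(7.25, 200)
  expect_equal(smooth_series(const), const)
  expect_equal(ema(const, 151), const)
  expect_equal(remove_outliers(const), const)

  # Savitzky-Golay with window = degree + 1 interpolates exactly
  set.seed(9)
  y <- runif(50)
  expect_equal(as.numeric(signal::sgolayfilt(y, p = 8, n = 9)), y,
               tolerance = 1e-8)

  # single 100x spike: brute-force z-scores flag it, interpolation removes it
  x <- rep(2, 101); x[51] <- 200
  z <- (x - mean(x)) / sd(x)
  expect_true(abs(z[51]) > 3)  # oracle: the spike is the flagged point
  cleaned <- remove_outliers(x, z_threshold = 3)
  expect_false(which.max(cleaned) == 51 && max(cleaned) > max(cleaned[-51]))
  expect_equal(cleaned[51], 2)  # neighbors are both 2

  expect_error(smooth_series(rep(1, 10), savgol_window = 31), "length")
  expect_error(smooth_series(rep(1, 100), savgol_window = 30), "odd")
})

test_that("impact weighting and user mean follow the definitions", {
  expect_equal(tweetwise_engagement(c(2, 4), 0.5), c(1, 2))
  expect_equal(tweetwise_engagement(c(2, 4), 0), c(0, 0))
  expect_equal(tweetwise_engagement(c(2, 4), 1), c(2, 4))
  expect_equal(user_engagement(c(1, 2, 3)), 2)
  expect_equal(user_engagement(5), 5)
  expect_equal(user_engagement(c(0, 0)), 0)
  expect_error(user_engagement(numeric()), "empty")
})

test_that("daily aggregation equals a per-tweet brute-force loop", {
  cfg <- simulation_config(seed = 11,
                           window = analysis_window("2020-01-01", "2020-02-29"),
                           n_leaders = 2, n_health_orgs = 1,
                           tweets_per_day = c(leader = 1, health_org = 2),
                           dual_handle_first_leader = FALSE)
  co <- simulate_cohort(cfg)
  co$tweets$user_id <- co$roster$user_id[match(co$tweets$author_handle,
                                               co$roster$handle)]
  daily <- daily_engagement(co$tweets)
  # brute force: accumulate per (user, date) one tweet at a time
  acc <- new.env()
  for (i in seq_len(nrow(co$tweets))) {
    key <- paste(co$tweets$user_id[i],
                 as.Date(co$tweets$created_at[i], tz = "UTC"))
    prev <- if (is.null(acc[[key]])) c(0, 0) else acc[[key]]
    acc[[key]] <- prev + c(co$tweets$like_count[i] + co$tweets$reply_count[i] +
                             co$tweets$retweet_count[i] + co$tweets$quote_count[i], 1)
  }
  for (j in seq_len(nrow(daily))) {
    key <- paste(daily$user_id[j], daily$date[j])
    expect_equal(daily$raw_daily_avg[j], acc[[key]][1] / (4 * acc[[key]][2]))
  }
  expect_equal(nrow(daily), length(ls(acc)))
})

test_that("raising any single count never decreases user engagement (no smoothing)", {
  set.seed(21)
  tw <- toy_tweets()
  tw$user_id <- "u1"
  imp <- tibble::tibble(user_id = "u1", impact = 0.8)
  base_series <- engagement_series(daily_engagement(tw), imp, smooth = FALSE)
  base <- user_engagement(base_series$impact_weighted)
  for (f in c("like_count", "reply_count", "retweet_count", "quote_count")) {
    bumped <- tw
    i <- sample(nrow(tw), 1)
    bumped[[f]][i] <- bumped[[f]][i] + 50L
    s <- engagement_series(daily_engagement(bumped), imp, smooth = FALSE)
    expect_gte(user_engagement(s$impact_weighted), base)
  }
})
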
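test_that("the composite is a plain product with sentinel passthrough", {
  expect_equal(compose_osa(2.0, 0.5, 0.25), 0.25)
  expect_equal(compose_osa(0, 0.5, 0.25), 0)
  expect_equal(compose_osa(1.0, 1e-6, 1.0), 1e-6)
  expect_equal(compose_osa(3, -0.5, 0.5), -0.75)  # sign follows sentiment
  expect_error(compose_osa(1, 0.5, 0), "positive")
  expect_error(compose_osa(1, 1.5, 0.5), "sentiment")
})

test_that("group-max normalization maps each group top to exactly 1", {
  df <- tibble::tibble(user_id = c("a", "b", "c", "x", "y"),
                       group = c(rep("leader", 3), rep("health_org", 2)),
                       raw_osa = c(10, 0.68, 0.33, 4, 2))
  n <- normalize_within_group(df)
  expect_equal(n$normalized_osa[match(c("a", "b", "c"), n$user_id)],
               c(1.0, 0.068, 0.033))
  expect_equal(n$normalized_osa[n$user_id == "x"], 1.0)
  # singleton positive group
  single <- tibble::tibble(user_id = "s", group = "leader", raw_osa = 0.4)
  expect_equal(normalize_within_group(single)$normalized_osa, 1.0)
  # negatives stay negative; all-nonpositive group errors
  mixed <- tibble::tibble(user_id = c("p", "q"), group = "leader",
                          raw_osa = c(2, -1))
  expect_equal(normalize_within_group(mixed)$normalized_osa, c(1, -0.5))
  allneg <- tibble::tibble(user_id = c("p", "q"), group = "leader",
                           raw_osa = c(-2, -1))
  expect_error(normalize_within_group(allneg), "raw OSA")
})

test_that("normalization is scale-invariant and rank-preserving", {
  set.seed(17)
  df <- tibble::tibble(user_id = sprintf("u%02d", 1:8),
                       group = rep(c("leader", "health_org"), each = 4),
                       raw_osa = runif(8, 0.01, 5))
  n1 <- normalize_within_group(df)
  df2 <- df; df2$raw_osa <- df2$raw_osa * 37.5
  n2 <- normalize_within_group(df2)
  expect_equal(n1$normalized_osa, n2$normalized_osa)
  for (g in unique(df$group)) {
    i <- which(df$group == g)
    expect_equal(order(n1$raw_osa[i]), order(n1$normalized_osa[i]))
  }
})

test_that("rank report truncates deterministically with user_id tie-break", {
  df <- tibble::tibble(user_id = c("b", "a", "c", "d"),
                       group = "leader",
                       raw_osa = c(0.5, 0.5, 1, 0.1))
  n <- normalize_within_group(df)
  r <- rank_report(n, k = 3)
  expect_equal(r$user_id, c("c", "a", "b"))  # tie at 0.5 -> lexicographic
  expect_equal(r$rank, 1:3)
  expect_equal(nrow(rank_report(n, k = 10)), 4)  # k beyond group size
  expect_error(rank_report(n, k = 0), "k")
})

test_that("a user dominating every component ranks first end to end", {
  cfg <- simulation_config(seed = 23,
                           window = analysis_window("2020-01-01", "2020-04-09"))
  targets <- data.frame(
    user_id = c("dominant", "middling", "weak"),
    n_tweets = c(100, 100, 100),
    sentiment_fraction = c(0.9, 0.6, 0.52),
    mention_fraction = c(0.9, 0.4, 0.1))
  co <- plant_known_strengths(cfg, targets)
  # hand the dominant user strictly larger engagement too
  dom <- co$tweets$author_handle == "dominant"
  co$tweets$like_count[dom] <- co$tweets$like_count[dom] + 5000L
  res <- score_cohort(co$tweets, co$profiles, co$roster, window = cfg$window,
                      smooth = FALSE)
  expect_equal(res$user_id[1], "dominant")
  expect_equal(res$normalized_osa[1], 1.0)
  # planted strengths recovered exactly alongside
  expect_equal(res$senti_strength[match(targets$user_id, res$user_id)],
               targets$sentiment_fraction)
  expect_equal(res$id_strength[match(targets$user_id, res$user_id)],
               targets$mention_fraction)
})

test_that("pipeline scores equal the brute-force per-tweet oracle", {
  # many small seeded corpora, smoothing off, exact agreement expected
  for (seed in c(101, 202, 303)) {
    cfg <- simulation_config(seed = seed,
                             window = analysis_window("2020-02-01", "2020-03-15"),
                             n_leaders = 2, n_health_orgs = 2,
                             tweets_per_day = c(leader = 1.2, health_org = 1.8),
                             dual_handle_first_leader = FALSE)
    co <- simulate_cohort(cfg)
    expect_lte(nrow(co$tweets), 400)
    res <- score_cohort(co$tweets, co$profiles, co$roster, window = cfg$window,
                        smooth = FALSE)
    oracle <- brute_force_scores(co$tweets, co$profiles, co$roster, cfg$window,
                                 default_community_lexicon(),
                                 lexicon_classifier())
    res <- res[order(res$user_id), ]
    expect_equal(res$raw_impact, oracle$raw_impact)
    expect_equal(res$scaled_impact, oracle$scaled_impact)
    expect_equal(res$senti_strength, oracle$senti_strength)
    expect_equal(res$id_strength, oracle$id_strength)
    expect_equal(res$daily_avg_eng_user,
                 oracle$scaled_impact * oracle$series_sum / oracle$n_days)
    expect_equal(res$raw_osa, oracle$raw_osa)
    expect_equal(res$normalized_osa, oracle$normalized_osa)
  }
})
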
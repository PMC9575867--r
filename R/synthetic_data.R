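#' Configure a synthetic tweet cohort
#'
#' The generator emulates the statistical structure the scoring pipeline
#' assumes in crisis-period tweet streams from public accounts: per-user
#' daily tweet counts (Poisson), overdispersed per-tweet engagement
#' (negative binomial) with occasional event-driven spike days, a
#' categorical sentiment mixture realized as planted lexicon tokens (so the
#' bundled fallback classifier recovers each label exactly), and Bernoulli
#' community-keyword mentions. Defaults reflect a two-year crisis window
#' with ten leaders and ten health organizations; organization accounts
#' tweet more often but draw less engagement per tweet, leaders the reverse,
#' giving a corpus on the order of 1.7e5 tweets at full scale.
#'
#' @param seed Integer seed; the whole simulation runs on one stream seeded
#'   once, so equal seeds give byte-identical corpora.
#' @param window An [analysis_window()].
#' @param n_leaders,n_health_orgs Users per group.
#' @param tweets_per_day Named mean tweets/day per group (Poisson rates).
#' @param engagement_mean Named mean total interactions per tweet per group
#'   (negative-binomial mu).
#' @param engagement_dispersion Negative-binomial size parameter; small
#'   values give the heavy overdispersion typical of engagement counts.
#' @param spike_schedule Data frame `date, multiplier`: on listed days the
#'   engagement mean is multiplied, emulating event-driven surges.
#' @param sentiment_mix Probability triple `c(negative, neutral, positive)`
#'   applied per tweet; must sum to 1.
#' @param mention_prob Probability a tweet embeds a community keyword.
#' @param vocab List with character vectors `hashtags` and `mentions` to
#'   sprinkle into texts.
#' @param dual_handle_first_leader Give the first leader a second handle
#'   (tweets split across both), exercising handle merging.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(seed = 1,
                              window = analysis_window(),
                              n_leaders = 10,
                              n_health_orgs = 10,
                              tweets_per_day = c(leader = 4.8, health_org = 17.9),
                              engagement_mean = c(leader = 150, health_org = 30),
                              engagement_dispersion = 0.5,
                              spike_schedule = data.frame(
                                date = as.Date(c("2020-04-10", "2020-08-21",
                                                 "2020-10-30")),
                                multiplier = c(6, 8, 5)),
                              sentiment_mix = c(negative = 0.2, neutral = 0.5,
                                                positive = 0.3),
                              mention_prob = 0.3,
                              vocab = list(
                                hashtags = c("covid19", "covid_19", "coronavirus",
                                             "yomevacuno", "stayhome", "vaccines",
                                             "budget2021", "cop25", "tokyo2020"),
                                mentions = c("who", "govcanhealth", "ukhsa",
                                             "mohapuae", "saglikbakanligi",
                                             "minsaludcol")),
                              dual_handle_first_leader = TRUE) {
  cfg <- list(seed = as.integer(seed), window = window,
              n_leaders = as.integer(n_leaders),
              n_health_orgs = as.integer(n_health_orgs),
              tweets_per_day = tweets_per_day,
              engagement_mean = engagement_mean,
              engagement_dispersion = engagement_dispersion,
              spike_schedule = spike_schedule,
              sentiment_mix = sentiment_mix,
              mention_prob = mention_prob,
              vocab = vocab,
              dual_handle_first_leader = isTRUE(dual_handle_first_leader))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$window, "osa_window"))
  if (abs(sum(cfg$sentiment_mix) - 1) > 1e-9) {
    stop("simulation_config: sentiment_mix must sum to 1", call. = FALSE)
  }
  if (any(cfg$sentiment_mix < 0) || any(cfg$sentiment_mix > 1)) {
    stop("simulation_config: sentiment_mix probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$mention_prob < 0 || cfg$mention_prob > 1) {
    stop("simulation_config: mention_prob must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$tweets_per_day < 0) || any(cfg$engagement_mean < 0) ||
      cfg$engagement_dispersion <= 0) {
    stop("simulation_config: rates must be non-negative and dispersion positive",
         call. = FALSE)
  }
  if (cfg$n_leaders < 1 || cfg$n_health_orgs < 0) {
    stop("simulation_config: need at least one leader", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

SIM_COUNTRIES <- c("Chile", "Ireland", "UAE", "Finland", "Canada",
                   "Colombia", "Turkey", "Spain", "Sweden", "UK")

# fixed multinomial split of total interactions across the four count
# fields (likes-heavy); the composite only ever sums them, so the split is a
# free choice of the generator
ENGAGEMENT_SPLIT <- c(likes = 0.6, replies = 0.1, retweets = 0.25, quotes = 0.05)

split_interactions <- function(total) {
  likes <- rbinom(length(total), total, ENGAGEMENT_SPLIT[["likes"]])
  rem <- total - likes
  replies <- rbinom(length(total), rem, ENGAGEMENT_SPLIT[["replies"]] /
                      (1 - ENGAGEMENT_SPLIT[["likes"]]))
  rem <- rem - replies
  retweets <- rbinom(length(total), rem, ENGAGEMENT_SPLIT[["retweets"]] /
                       (ENGAGEMENT_SPLIT[["retweets"]] + ENGAGEMENT_SPLIT[["quotes"]]))
  quotes <- rem - retweets
  tibble::tibble(like_count = likes, reply_count = replies,
                 retweet_count = retweets, quote_count = quotes)
}

sim_terms <- function() {
  lex <- default_sentiment_lexicon()
  list(positive = lex$term[lex$polarity == 1],
       negative = lex$term[lex$polarity == -1],
       keywords = default_community_lexicon()$keyword)
}

#' Simulate a seeded tweet cohort
#'
#' Draws a full corpus of tweets, per-handle profiles and a roster under one
#' random stream seeded from the config, so the output is fully
#' deterministic for a fixed seed. Sentiment is realized by planting one
#' positive or negative lexicon token (neutral tweets contain none), so the
#' bundled fallback classifier recovers the drawn label exactly; with
#' probability `mention_prob` a community keyword is embedded.
#'
#' @param config A [simulation_config()].
#' @return A list with tibbles `tweets` (flat tweet dialect, keyed by
#'   `author_handle`), `profiles` (per handle), `roster`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  terms <- sim_terms()
  dates <- seq(config$window$start_date, config$window$end_date, by = "day")
  mult <- rep(1, length(dates))
  sched <- config$spike_schedule
  hit <- match(as.Date(sched$date), dates)
  mult[hit[!is.na(hit)]] <- sched$multiplier[!is.na(hit)]

  users <- tibble::tibble(
    user_id = c(sprintf("leader%02d", seq_len(config$n_leaders)),
                sprintf("health%02d", seq_len(config$n_health_orgs))),
    group = rep(c("leader", "health_org"),
                c(config$n_leaders, config$n_health_orgs)),
    country = c(rep_len(SIM_COUNTRIES, config$n_leaders),
                rep_len(SIM_COUNTRIES, config$n_health_orgs))
  )

  tweet_blocks <- vector("list", nrow(users))
  profile_rows <- list()
  roster_rows <- list()
  for (i in seq_len(nrow(users))) {
    u <- users[i, ]
    rate <- config$tweets_per_day[[u$group]]
    mu <- config$engagement_mean[[u$group]]
    n_day <- rpois(length(dates), rate)
    n <- sum(n_day)
    day_idx <- rep(seq_along(dates), n_day)

    handles <- u$user_id
    dual <- config$dual_handle_first_leader && u$group == "leader" && i == 1
    if (dual) handles <- c(handles, paste0(u$user_id, "_office"))
    handle_of_tweet <- if (dual && n > 0) {
      handles[1 + (runif(n) < 0.3)]
    } else rep(handles[1], max(n, 0))

    total <- rnbinom(n, size = config$engagement_dispersion,
                     mu = mu * mult[day_idx])
    counts <- split_interactions(total)

    lab <- sample(SENTIMENT_LABELS, n, replace = TRUE,
                  prob = config$sentiment_mix[c("negative", "neutral", "positive")])
    senti_tok <- character(n)
    senti_tok[lab == "positive"] <- sample(terms$positive, sum(lab == "positive"),
                                           replace = TRUE)
    senti_tok[lab == "negative"] <- sample(terms$negative, sum(lab == "negative"),
                                           replace = TRUE)
    kw <- ifelse(runif(n) < config$mention_prob,
                 sample(terms$keywords, n, replace = TRUE), "")
    tag <- ifelse(runif(n) < 0.4,
                  paste0("#", sample(config$vocab$hashtags, n, replace = TRUE)), "")
    men <- ifelse(runif(n) < 0.25,
                  paste0("@", sample(config$vocab$mentions, n, replace = TRUE)), "")
    text <- trimws(stringr::str_squish(paste(
      sprintf("situation report %d from the %s office", seq_len(n), u$country),
      senti_tok, kw, tag, men)))

    tweet_blocks[[i]] <- tibble::tibble(
      author_handle = handle_of_tweet,
      created_at = as.POSIXct(dates[day_idx], tz = "UTC") +
        round(runif(n, 0, 86399)),
      text = text,
      like_count = counts$like_count, reply_count = counts$reply_count,
      retweet_count = counts$retweet_count, quote_count = counts$quote_count,
      lang = "en"
    )

    base_followers <- if (u$group == "leader") 10^runif(1, 5, 7.5) else 10^runif(1, 4.5, 6.5)
    for (j in seq_along(handles)) {
      fol <- round(base_followers * if (j == 1) 1 else runif(1, 0.05, 0.3))
      profile_rows[[length(profile_rows) + 1]] <- tibble::tibble(
        handle = handles[j],
        display_name = paste(u$country, if (u$group == "leader") "Leader" else "Health Agency"),
        followers = max(fol, 10),
        following = sample(20:2000, 1),
        listed_count = round(max(fol, 10) * runif(1, 2e-4, 2e-3)),
        total_tweet_count = sum(handle_of_tweet == handles[j]),
        profile_created_at = config$window$start_date - sample(800:4500, 1)
      )
      roster_rows[[length(roster_rows) + 1]] <- tibble::tibble(
        handle = handles[j], user_id = u$user_id, group = u$group,
        country = u$country, primary = j == 1)
    }
  }

  tweets <- dplyr::bind_rows(tweet_blocks)
  tweets <- tibble::add_column(tweets,
                               tweet_id = sprintf("t%08d", seq_len(nrow(tweets))),
                               .before = 1)
  list(tweets = validate_tweets(tweets),
       profiles = dplyr::bind_rows(profile_rows),
       roster = validate_roster(dplyr::bind_rows(roster_rows)),
       config = config)
}

#' Plant analytically known component strengths
#'
#' Builds a cohort whose sentiment and inclusivity strengths are known in
#' closed form: label and keyword counts are *placed*, not sampled, so the
#' downstream statistics equal the planted fractions exactly. Engagement
#' counts are still drawn from the configured negative binomial (under the
#' config seed) since only the label/keyword structure needs to be exact.
#'
#' @param config A [simulation_config()]; supplies the window, seed and
#'   engagement model.
#' @param targets Data frame with one row per user: `n_tweets`;
#'   `sentiment_fraction` (signed: +0.6 plants a 60% positive majority,
#'   -0.4 a 40% negative majority, 0 an all-neutral user); and
#'   `mention_fraction`. Optional `user_id` and `group` columns. Fractions
#'   must be exactly expressible at `n_tweets` and the planted class must be
#'   a strict majority, else an error.
#' @return A cohort list as from [simulate_cohort()], plus `targets`.
#' @export
plant_known_strengths <- function(config, targets) {
  config <- validate_sim_config(config)
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("n_tweets", "sentiment_fraction", "mention_fraction") %in%
                  names(targets)))
  if (!"user_id" %in% names(targets)) {
    targets$user_id <- sprintf("planted%02d", seq_len(nrow(targets)))
  }
  if (!"group" %in% names(targets)) targets$group <- "leader"
  set.seed(config$seed)

  dates <- seq(config$window$start_date, config$window$end_date, by = "day")
  tweet_blocks <- vector("list", nrow(targets))
  profile_rows <- vector("list", nrow(targets))
  roster_rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    n <- as.integer(tg$n_tweets)
    labels <- plant_labels(tg$sentiment_fraction, n)
    n_kw <- tg$mention_fraction * n
    if (abs(n_kw - round(n_kw)) > 1e-9) {
      stop(sprintf("mention_fraction %g not expressible at %d tweets",
                   tg$mention_fraction, n), call. = FALSE)
    }
    has_kw <- seq_len(n) <= round(n_kw)

    senti_tok <- c(negative = "terrible", neutral = "", positive = "hopeful")[labels]
    text <- trimws(paste(sprintf("planted tweet %d", seq_len(n)), senti_tok,
                         ifelse(has_kw, "nurses", "")))
    total <- rnbinom(n, size = config$engagement_dispersion,
                     mu = config$engagement_mean[[1]])
    counts <- split_interactions(total)
    day_idx <- floor(seq(1, length(dates), length.out = n))
    tweet_blocks[[i]] <- tibble::tibble(
      author_handle = tg$user_id,
      created_at = as.POSIXct(dates[day_idx], tz = "UTC") + 43200,
      text = stringr::str_squish(text),
      like_count = counts$like_count, reply_count = counts$reply_count,
      retweet_count = counts$retweet_count, quote_count = counts$quote_count,
      lang = "en"
    )
    # identical profile metrics across planted users: tanh saturates, raw
    # impacts tie, and the degenerate min-max rule scales every impact to 1,
    # so the planted sentiment/mention fractions alone drive the ranking
    profile_rows[[i]] <- tibble::tibble(
      handle = tg$user_id, display_name = tg$user_id,
      followers = 50000, following = 100, listed_count = 50,
      total_tweet_count = n,
      profile_created_at = config$window$start_date - 1000)
    roster_rows[[i]] <- tibble::tibble(handle = tg$user_id, user_id = tg$user_id,
                                       group = tg$group,
                                       country = "all", primary = TRUE)
  }
  tweets <- dplyr::bind_rows(tweet_blocks)
  tweets <- tibble::add_column(tweets,
                               tweet_id = sprintf("p%08d", seq_len(nrow(tweets))),
                               .before = 1)
  list(tweets = validate_tweets(tweets),
       profiles = dplyr::bind_rows(profile_rows),
       roster = validate_roster(dplyr::bind_rows(roster_rows)),
       config = config, targets = targets)
}

# exact label placement: majority class count = |fraction| * n, remainder
# split so the planted class is a strict majority
plant_labels <- function(fraction, n) {
  if (abs(fraction) > 1) {
    stop("sentiment_fraction must lie in [-1, 1]", call. = FALSE)
  }
  n_major_real <- abs(fraction) * n
  if (abs(n_major_real - round(n_major_real)) > 1e-9) {
    stop(sprintf("sentiment_fraction %g not expressible at %d tweets",
                 fraction, n), call. = FALSE)
  }
  if (fraction == 0) return(rep("neutral", n))
  n_major <- as.integer(round(n_major_real))
  others <- n - n_major
  n_a <- ceiling(others / 2)
  n_b <- floor(others / 2)
  if (n_major <= n_a) {
    stop(sprintf("sentiment_fraction %g cannot form a strict majority at %d tweets",
                 fraction, n), call. = FALSE)
  }
  if (fraction > 0) {
    rep(c("positive", "neutral", "negative"), c(n_major, n_a, n_b))
  } else {
    rep(c("negative", "neutral", "positive"), c(n_major, n_a, n_b))
  }
}

#' Write a simulated cohort to disk
#'
#' Emits the same dialects the readers accept: tweets as JSON Lines or flat
#' CSV, profiles and roster as CSV, and the config as YAML.
#'
#' @param cohort A cohort list ([simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param dialect Tweet dialect to write.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("api_v2_jsonl", "flat_csv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tweets_path <- file.path(dir, if (dialect == "flat_csv") "tweets.csv"
                           else "tweets.jsonl")
  write_tweets(cohort$tweets, tweets_path, dialect)
  readr::write_csv(cohort$profiles, file.path(dir, "profiles.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$roster, file.path(dir, "roster.csv"), progress = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(
    seed = cfg$seed,
    window = list(start_date = as.character(cfg$window$start_date),
                  end_date = as.character(cfg$window$end_date),
                  reference_date = as.character(cfg$window$reference_date)),
    n_leaders = cfg$n_leaders, n_health_orgs = cfg$n_health_orgs,
    tweets_per_day = as.list(cfg$tweets_per_day),
    engagement_mean = as.list(cfg$engagement_mean),
    engagement_dispersion = cfg$engagement_dispersion,
    sentiment_mix = as.list(cfg$sentiment_mix),
    mention_prob = cfg$mention_prob
  ), file.path(dir, "config.yaml"))
  invisible(c(tweets = tweets_path,
              profiles = file.path(dir, "profiles.csv"),
              roster = file.path(dir, "roster.csv"),
              config = file.path(dir, "config.yaml")))
}
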
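# Independent brute-force oracle: recomputes every user-level statistic by
# looping over individual tweets with base R only, never touching the
# package's vectorized/grouped code paths. Used to cross-check the pipeline
# on small corpora.
brute_force_scores <- function(tweets, profiles, roster, window,
                               lexicon, classifier) {
  uid_of <- setNames(roster$user_id, roster$handle)
  ref <- window$reference_date
  users <- unique(roster$user_id)
  rows <- list()
  for (uid in users) {
    idx <- which(uid_of[tweets$author_handle] == uid &
                   as.Date(tweets$created_at, tz = "UTC") >= window$start_date &
                   as.Date(tweets$created_at, tz = "UTC") <= window$end_date)
    if (length(idx) == 0) next
    tw <- tweets[idx, ]
    dates <- as.Date(tw$created_at, tz = "UTC")

    # Eq. 5 per active day, one tweet at a time
    daily <- list()
    for (i in seq_len(nrow(tw))) {
      key <- as.character(dates[i])
      if (is.null(daily[[key]])) daily[[key]] <- c(sum = 0, n = 0)
      daily[[key]]["sum"] <- daily[[key]]["sum"] + tw$like_count[i] +
        tw$reply_count[i] + tw$retweet_count[i] + tw$quote_count[i]
      daily[[key]]["n"] <- daily[[key]]["n"] + 1
    }
    day_avg <- sapply(daily, function(d) d[["sum"]] / (4 * d[["n"]]))

    # dense per-user calendar with interior linear interpolation
    cal <- seq(min(dates), max(dates), by = "day")
    series <- rep(NA_real_, length(cal))
    series[match(as.Date(names(day_avg)), cal)] <- unname(day_avg)
    for (j in which(is.na(series))) {
      lo <- max(which(!is.na(series[1:j])))
      hi <- j + min(which(!is.na(series[(j + 1):length(series)])))
      series[j] <- series[lo] + (series[hi] - series[lo]) * (j - lo) / (hi - lo)
    }

    # Eq. 4 with in-window tweet count
    prow <- profiles[profiles$handle ==
                       roster$handle[roster$user_id == uid & roster$primary], ]
    age <- as.integer(ref - as.Date(prow$profile_created_at))
    raw_impact <- tanh(log10(sqrt(prow$followers) / prow$following) *
                         prow$listed_count * nrow(tw)) / age^2

    # Eq. 6 over the whole window
    labs <- classifier(tw$text)
    n_neg <- sum(labs == "negative"); n_neu <- sum(labs == "neutral")
    n_pos <- sum(labs == "positive")
    top <- max(n_neg, n_neu, n_pos)
    senti <- if (sum(c(n_neg, n_neu, n_pos) == top) > 1 || n_neu == top) 1e-6
             else if (n_pos == top) n_pos / nrow(tw) else -n_neg / nrow(tw)

    # Eq. 7, one tweet at a time
    kw <- lexicon$keyword[lexicon$country %in% c("all")]
    n_mention <- 0
    for (i in seq_len(nrow(tw))) {
      hit <- FALSE
      for (k in kw) {
        if (grepl(paste0("\\b", k, "\\b"), tolower(tw$text[i]), perl = TRUE)) {
          hit <- TRUE; break
        }
      }
      n_mention <- n_mention + hit
    }
    incl <- if (n_mention == 0) 1e-6 else n_mention / nrow(tw)

    rows[[uid]] <- data.frame(user_id = uid,
                              group = roster$group[roster$user_id == uid][1],
                              n_tweets = nrow(tw), raw_impact = raw_impact,
                              series_sum = sum(series), n_days = length(cal),
                              senti_strength = senti, id_strength = incl)
  }
  out <- do.call(rbind, rows)
  # min-max impact scaling and group-max OSA normalization, by hand
  out$scaled_impact <- NA_real_
  out$raw_osa <- NA_real_
  out$normalized_osa <- NA_real_
  for (g in unique(out$group)) {
    i <- out$group == g
    r <- out$raw_impact[i]
    out$scaled_impact[i] <- if (max(r) == min(r)) 1 else (r - min(r)) / (max(r) - min(r))
    eng <- out$scaled_impact[i] * out$series_sum[i] / out$n_days[i]  # Eqs. 3 + 2
    out$raw_osa[i] <- eng * out$senti_strength[i] * out$id_strength[i]
    out$normalized_osa[i] <- out$raw_osa[i] / max(out$raw_osa[i])
  }
  out[order(out$user_id), ]
}

# small deterministic hand-built corpus used across io/content tests
toy_tweets <- function() {
  tibble::tibble(
    tweet_id = sprintf("tt%02d", 1:6),
    author_handle = c("alice", "alice", "alice_alt", "bob", "bob", "bob"),
    created_at = as.POSIXct("2020-03-01 12:00:00", tz = "UTC") + (0:5) * 86400,
    text = c("Stay safe #COVID19 #covid19 @WHO",
             "no entities here",
             "#yomevacuno update",
             "thanks to the nurses #covid19",
             "a tragic loss",
             "briefing at noon @WHO @un"),
    like_count = c(3L, 0L, 5L, 10L, 2L, 1L),
    reply_count = c(1L, 0L, 2L, 2L, 1L, 0L),
    retweet_count = c(2L, 0L, 1L, 4L, 0L, 0L),
    quote_count = c(0L, 0L, 0L, 0L, 1L, 0L),
    lang = "en"
  )
}

toy_roster <- function() {
  tibble::tibble(
    handle = c("alice", "alice_alt", "bob"),
    user_id = c("u_alice", "u_alice", "u_bob"),
    group = c("leader", "leader", "health_org"),
    country = c("Canada", "Canada", "UK"),
    primary = c(TRUE, FALSE, TRUE)
  )
}

toy_profiles <- function() {
  tibble::tibble(
    handle = c("alice", "alice_alt", "bob"),
    display_name = c("Alice", "Alice Office", "Bob"),
    followers = c(100000, 5000, 20000),
    following = c(150, 40, 300),
    listed_count = c(120, 10, 60),
    total_tweet_count = c(3, 1, 3),
    profile_created_at = as.Date(c("2012-05-01", "2015-08-01", "2014-02-01"))
  )
}

toy_window <- function() analysis_window("2020-01-01", "2020-12-31", "2021-12-31")
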
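#' User impact score
#'
#' A bounded account-authority score: the hyperbolic tangent of the product
#' of the base-10 log follower/following ratio (`log10(sqrt(followers) /
#' following)`, logged to blunt outliers), the public list count, and the
#' number of tweets collected in the analysis window, divided by the square
#' of the profile age in days. A newly created account with a large audience
#' thereby outranks an old account with the same audience. Because tanh is
#' bounded, `|impact| < 1 / profile_age_days^2` always.
#'
#' @param followers,following,listed_count,tweet_count Account statistics;
#'   `tweet_count` is the number of tweets collected in the window, not the
#'   lifetime profile counter.
#' @param age_days Profile age in whole days ([profile_age_days()]).
#' @return Numeric raw impact (vectorized).
#' @examples
#' user_impact(1e6, 100, 50, 1000, 1000)  # ~ tanh(5e4) / 1e6 = 1e-6
#' @export
user_impact <- function(followers, following, listed_count, tweet_count,
                        age_days) {
  if (any(following < 1)) {
    stop("user_impact: following must be >= 1 (follower ratio undefined at 0)",
         call. = FALSE)
  }
  if (any(followers < 1)) {
    stop("user_impact: followers must be >= 1 (log of zero ratio undefined)",
         call. = FALSE)
  }
  if (any(age_days < 1)) {
    stop("user_impact: profile age must be >= 1 day", call. = FALSE)
  }
  if (any(listed_count < 0) || any(tweet_count < 0)) {
    stop("user_impact: listed_count and tweet_count must be non-negative",
         call. = FALSE)
  }
  tanh(log10(sqrt(followers) / following) * listed_count * tweet_count) /
    age_days^2
}

#' Min-max scale impacts within each user group
#'
#' Raw impacts are rescaled to `[0, 1]` separately per user group, so the
#' most impactful leader and the most impactful health organization both
#' score 1. Degenerate groups (a single user, or all raw impacts equal) map
#' to 1.0, following the convention that the top of a group scores 1.000.
#'
#' @param impacts Tibble with columns `user_id`, `group`, `raw_impact`.
#' @return The input with a `scaled_impact` column added.
#' @export
scale_impacts <- function(impacts) {
  if (nrow(impacts) == 0) stop("scale_impacts: empty group", call. = FALSE)
  impacts |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(scaled_impact = {
      rng <- range(.data$raw_impact)
      if (diff(rng) == 0) rep(1.0, dplyr::n())
      else (.data$raw_impact - rng[1]) / diff(rng)
    }) |>
    dplyr::ungroup()
}

#' Average engagement per day
#'
#' The day's pooled likes, replies, retweets and quotes divided by four times
#' the day's tweet count -- four being the number of engagement variables
#' pooled in the numerator, so a tweet whose every interaction type averages
#' `x` scores `x`.
#'
#' @param likes,replies,retweets,quotes Daily pooled counts (vectorized).
#' @param daily_tweet_count Tweets posted that day; must be >= 1 (days with
#'   no tweets have no engagement row at all).
#' @return Numeric daily average engagement.
#' @examples
#' daily_avg_engagement(10, 2, 4, 0, 1)  # 4
#' @export
daily_avg_engagement <- function(likes, replies, retweets, quotes,
                                 daily_tweet_count) {
  if (any(daily_tweet_count < 1)) {
    stop("daily_avg_engagement: daily_tweet_count must be >= 1", call. = FALSE)
  }
  (likes + replies + retweets + quotes) / (4 * daily_tweet_count)
}

#' Aggregate tweets into per-user daily engagement rows
#'
#' Groups tweets by user and UTC calendar date and pools the four engagement
#' counts. Days on which a user posted nothing produce no row.
#'
#' @param tweets Tweet tibble with a `user_id` column.
#' @return A tibble `user_id, date, likes, replies, retweets, quotes,
#'   daily_tweet_count, raw_daily_avg`.
#' @export
daily_engagement <- function(tweets) {
  stopifnot("user_id" %in% names(tweets))
  out <- tweets |>
    dplyr::mutate(date = as.Date(.data$created_at, tz = "UTC")) |>
    dplyr::group_by(.data$user_id, .data$date) |>
    dplyr::summarise(
      likes = sum(.data$like_count),
      replies = sum(.data$reply_count),
      retweets = sum(.data$retweet_count),
      quotes = sum(.data$quote_count),
      daily_tweet_count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$user_id, .data$date)
  out$raw_daily_avg <- daily_avg_engagement(out$likes, out$replies,
                                            out$retweets, out$quotes,
                                            out$daily_tweet_count)
  out
}

#' Exponential moving average
#'
#' Span-parameterized EMA with weight `alpha = 2 / (span + 1)` and
#' finite-history normalization: the value at position t is the
#' `(1-alpha)^i`-weighted average of observations 0..t, so early values are
#' not biased toward an arbitrary initialization. Constant series are fixed
#' points.
#'
#' @param x Numeric series.
#' @param span Window span in observations (days here); the default 151 is
#'   the span used for daily engagement standardization.
#' @return Smoothed series, same length.
#' @export
ema <- function(x, span = 151) {
  if (span < 1) stop("ema: span must be >= 1", call. = FALSE)
  alpha <- 2 / (span + 1)
  n <- length(x)
  out <- numeric(n)
  num <- 0
  den <- 0
  for (t in seq_len(n)) {
    num <- (1 - alpha) * num + x[t]
    den <- (1 - alpha) * den + 1
    out[t] <- num / den
  }
  out
}

#' Replace z-score outliers by linear interpolation
#'
#' Positions whose standardized deviation from the series mean exceeds the
#' threshold are replaced by linear interpolation of their neighbors (end
#' points take the nearest retained value). Replacing rather than deleting
#' keeps the calendar dense, which downstream filters require. A constant
#' series (zero standard deviation) is returned unchanged.
#'
#' @param x Numeric series.
#' @param z_threshold Flag positions with `|z| >` this; default 3.
#' @return Series of the same length with outliers interpolated.
#' @export
remove_outliers <- function(x, z_threshold = 3) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(x)
  z <- (x - mean(x)) / s
  keep <- abs(z) <= z_threshold
  if (all(keep)) return(x)
  x[!keep] <- NA_real_
  as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
}

#' Smooth a daily engagement series
#'
#' The standardization chain applied to each user's daily average
#' engagement, in order: exponential moving average ([ema()]), z-score
#' outlier replacement ([remove_outliers()]), then Savitzky-Golay polynomial
#' smoothing (`signal::sgolayfilt`). The polynomial degree defaults to 8;
#' the filter window must be odd and larger than the degree (default 31
#' days). Constant series pass through every stage unchanged.
#'
#' @param x Numeric series (dense daily values, no gaps).
#' @param ema_span EMA span in days (default 151).
#' @param z_threshold Outlier threshold (default 3).
#' @param savgol_window Savitzky-Golay window length, odd, > degree
#'   (default 31).
#' @param savgol_degree Savitzky-Golay polynomial degree (default 8).
#' @return Smoothed series of the same length, finite everywhere.
#' @export
smooth_series <- function(x, ema_span = 151, z_threshold = 3,
                          savgol_window = 31, savgol_degree = 8) {
  if (savgol_window %% 2 != 1 || savgol_window <= savgol_degree) {
    stop("smooth_series: savgol_window must be odd and greater than savgol_degree",
         call. = FALSE)
  }
  if (length(x) <= savgol_window) {
    stop(sprintf(paste0("smooth_series: series length %d must exceed the ",
                        "Savitzky-Golay window %d; configure a smaller ",
                        "savgol_window for short series"),
                 length(x), savgol_window), call. = FALSE)
  }
  y <- ema(x, span = ema_span)
  y <- remove_outliers(y, z_threshold = z_threshold)
  y <- as.numeric(signal::sgolayfilt(y, p = savgol_degree, n = savgol_window))
  if (!all(is.finite(y))) {
    stop("smooth_series: non-finite values after filtering", call. = FALSE)
  }
  y
}

#' Impact-weighted engagement
#'
#' Elementwise product of a user's daily average engagement with their
#' impact score.
#'
#' @param daily Numeric series of daily average engagement.
#' @param impact Scalar impact score.
#' @return Numeric series.
#' @export
tweetwise_engagement <- function(daily, impact) {
  daily * impact
}

#' User-level engagement
#'
#' Arithmetic mean of the impact-weighted daily engagement over the user's
#' retained calendar dates.
#'
#' @param impact_weighted Numeric series.
#' @return Scalar mean.
#' @export
user_engagement <- function(impact_weighted) {
  if (length(impact_weighted) == 0) {
    stop("user_engagement: empty series", call. = FALSE)
  }
  mean(impact_weighted)
}

#' Build per-user engagement series
#'
#' For each user, re-indexes the daily engagement rows onto a dense calendar
#' from the user's first to last active day (interior zero-tweet days carry
#' no defined daily average, so they are filled by linear interpolation),
#' optionally smooths the raw series ([smooth_series()]), and multiplies by
#' the user's impact score. Smoothing precedes impact weighting; the weight
#' is a per-user constant, so the order only changes the series by that
#' constant factor.
#'
#' @param daily Output of [daily_engagement()].
#' @param impacts Tibble `user_id, impact` giving each user's weight (raw or
#'   scaled impact, per the caller's configuration).
#' @param smooth Apply the smoothing chain? Series no longer than
#'   `savgol_window` raise an error when `TRUE`.
#' @inheritParams smooth_series
#' @return A tibble `user_id, date, raw_daily_avg, smoothed_daily_avg,
#'   impact_weighted` on the dense per-user calendar.
#' @export
engagement_series <- function(daily, impacts, smooth = TRUE, ema_span = 151,
                              z_threshold = 3, savgol_window = 31,
                              savgol_degree = 8) {
  impact_of <- setNames(impacts$impact, impacts$user_id)
  per_user <- split(daily, daily$user_id)
  rows <- lapply(per_user, function(d) {
    cal <- seq(min(d$date), max(d$date), by = "day")
    raw <- rep(NA_real_, length(cal))
    raw[match(d$date, cal)] <- d$raw_daily_avg
    raw <- as.numeric(zoo::na.approx(raw, na.rm = FALSE))
    sm <- if (smooth) {
      smooth_series(raw, ema_span = ema_span, z_threshold = z_threshold,
                    savgol_window = savgol_window, savgol_degree = savgol_degree)
    } else raw
    uid <- d$user_id[1]
    imp <- unname(impact_of[uid])
    if (length(imp) != 1 || is.na(imp)) {
      stop(sprintf("engagement_series: no impact score for user '%s'", uid),
           call. = FALSE)
    }
    tibble::tibble(user_id = uid, date = cal, raw_daily_avg = raw,
                   smoothed_daily_avg = sm,
                   impact_weighted = tweetwise_engagement(sm, imp))
  })
  dplyr::bind_rows(rows)
}
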
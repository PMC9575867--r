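#' Compose the online societal association score
#'
#' The raw composite is the plain, equally weighted product of the three
#' components: user-level impact-weighted daily engagement, sentiment
#' strength, and inclusivity-and-diversity strength. The sign follows the
#' sentiment sign (inclusivity is always positive); the neutral and
#' zero-mention sentinels (`1e-6`) pass through multiplicatively.
#'
#' @param eng User engagement ([user_engagement()]).
#' @param senti Sentiment strength in `[-1, 1]`.
#' @param incl Inclusivity strength in `(0, 1]` (or the `1e-6` sentinel).
#' @return Numeric raw OSA (vectorized).
#' @examples
#' compose_osa(2.0, 0.5, 0.25)  # 0.25
#' @export
compose_osa <- function(eng, senti, incl) {
  if (any(incl <= 0)) {
    stop("compose_osa: inclusivity strength must be positive (sentinel 1e-6 for zero mentions)",
         call. = FALSE)
  }
  if (any(abs(senti) > 1)) {
    stop("compose_osa: |sentiment strength| must be <= 1", call. = FALSE)
  }
  eng * senti * incl
}

#' Normalize OSA scores within each user group
#'
#' Leaders and health organizations are never scaled against each other.
#' The default method divides by the group maximum, so the top user of each
#' group scores exactly 1.000 and other users are reported as a fraction of
#' the top; negative composites (negative-majority sentiment) stay negative,
#' since the sign is information. `"minmax"` is available as an alternative
#' convention.
#'
#' @param results Tibble with `group` and `raw_osa` columns.
#' @param method `"group_max"` (default) or `"minmax"`.
#' @return The input with a `normalized_osa` column added.
#' @export
normalize_within_group <- function(results, method = c("group_max", "minmax")) {
  method <- match.arg(method)
  if (nrow(results) == 0) stop("normalize_within_group: empty input", call. = FALSE)
  results |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(normalized_osa = {
      if (max(.data$raw_osa) <= 0) {
        stop(sprintf("normalize_within_group: all raw OSA <= 0 in group '%s'; report raw scores only",
                     .data$group[1]), call. = FALSE)
      }
      if (method == "group_max") {
        .data$raw_osa / max(.data$raw_osa)
      } else {
        rng <- range(.data$raw_osa)
        if (diff(rng) == 0) rep(1.0, dplyr::n())
        else (.data$raw_osa - rng[1]) / diff(rng)
      }
    }) |>
    dplyr::ungroup()
}

#' Top-k ranking table per user group
#'
#' @param results OSA result tibble ([score_cohort()]).
#' @param k Rows to keep per group (default 10).
#' @return Results ordered within group by descending normalized OSA, ties
#'   broken by `user_id`, truncated to `k` rows per group, with a `rank`
#'   column.
#' @export
rank_report <- function(results, k = 10) {
  if (k < 1) stop("rank_report: k must be >= 1", call. = FALSE)
  results |>
    dplyr::arrange(.data$group, dplyr::desc(.data$normalized_osa), .data$user_id) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

#' Score a tweet cohort end to end
#'
#' Runs the full pipeline on a corpus of tweets, per-handle profiles and a
#' roster: merges handles into canonical users, restricts to the analysis
#' window, computes each user's impact (scaled to `[0, 1]` within group),
#' daily average engagement with the smoothing chain, sentiment strength via
#' the pluggable classifier, inclusivity strength against the community
#' lexicon, and finally the composite OSA normalized within each user group.
#'
#' @param tweets Canonical tweet tibble ([read_tweets()]).
#' @param profiles Per-handle profile tibble ([read_profiles()]).
#' @param roster Roster tibble ([read_roster()]).
#' @param window An [analysis_window()].
#' @param lexicon Community lexicon; defaults to the bundled starter list.
#' @param classifier Sentiment classifier; defaults to the bundled
#'   signed-lexicon scorer.
#' @param sentiment_mode `"window"` or `"daily_majority"` (see
#'   [user_sentiment()]).
#' @param use_scaled_impact Weight engagement by the within-group scaled
#'   impact (default) rather than the raw impact; raw impacts are of order
#'   `1/age^2` and serve ranking, while the scaled score keeps engagement
#'   curves on an interpretable scale.
#' @param smooth Apply the smoothing chain to daily engagement.
#' @param normalization Within-group normalization method.
#' @inheritParams smooth_series
#' @return A tibble, one row per canonical user: `user_id, group, country,
#'   n_tweets, raw_impact, scaled_impact, daily_avg_eng_user,
#'   senti_strength, id_strength, raw_osa, normalized_osa`. The per-day
#'   series are attached as attribute `"series"`.
#' @export
score_cohort <- function(tweets, profiles, roster, window = analysis_window(),
                         lexicon = default_community_lexicon(),
                         classifier = lexicon_classifier(),
                         sentiment_mode = c("window", "daily_majority"),
                         use_scaled_impact = TRUE, smooth = TRUE,
                         ema_span = 151, z_threshold = 3, savgol_window = 31,
                         savgol_degree = 8,
                         normalization = c("group_max", "minmax")) {
  sentiment_mode <- match.arg(sentiment_mode)
  normalization <- match.arg(normalization)
  if (nrow(tweets) == 0) stop("score_cohort: no tweets to score", call. = FALSE)

  merged <- merge_handles(profiles, tweets, roster)
  tw <- merged$tweets
  prof <- merged$profiles
  d <- as.Date(tw$created_at, tz = "UTC")
  tw <- tw[d >= window$start_date & d <= window$end_date, ]
  if (nrow(tw) == 0) {
    stop("score_cohort: no tweets inside the analysis window", call. = FALSE)
  }

  # impact: in-window collected tweet count, age anchored at the reference date
  counts <- dplyr::count(tw, .data$user_id, name = "n_tweets")
  prof <- dplyr::inner_join(prof, counts, by = "user_id")
  prof$age_days <- profile_age_days(prof$profile_created_at, window)
  prof$raw_impact <- user_impact(prof$followers, prof$following,
                                 prof$listed_count, prof$n_tweets,
                                 prof$age_days)
  prof <- scale_impacts(prof)
  prof$impact_used <- if (use_scaled_impact) prof$scaled_impact else prof$raw_impact

  daily <- daily_engagement(tw)
  series <- engagement_series(
    daily,
    impacts = tibble::tibble(user_id = prof$user_id, impact = prof$impact_used),
    smooth = smooth, ema_span = ema_span, z_threshold = z_threshold,
    savgol_window = savgol_window, savgol_degree = savgol_degree
  )
  eng <- series |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(daily_avg_eng_user = user_engagement(.data$impact_weighted),
                     .groups = "drop")

  labels <- classify_sentiment(tw$text, classifier)
  senti <- user_sentiment(tw, labels, mode = sentiment_mode)

  incl <- user_inclusivity(tw, lexicon,
                           countries = setNames(prof$country, prof$user_id))

  out <- prof[, c("user_id", "group", "country", "n_tweets",
                  "raw_impact", "scaled_impact")] |>
    dplyr::inner_join(eng, by = "user_id") |>
    dplyr::inner_join(senti[, c("user_id", "senti_strength")], by = "user_id") |>
    dplyr::inner_join(incl[, c("user_id", "id_strength")], by = "user_id")
  out$raw_osa <- compose_osa(out$daily_avg_eng_user, out$senti_strength,
                             out$id_strength)
  out <- normalize_within_group(out, method = normalization)
  out <- dplyr::arrange(out, .data$group, dplyr::desc(.data$normalized_osa),
                        .data$user_id)
  attr(out, "series") <- series
  out
}
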
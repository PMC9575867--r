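#' Define an analysis window
#'
#' The window bounds daily aggregation and fixes the reference date against
#' which profile age is measured. Defaults cover the COVID-19 crisis period
#' from the start of December 2019 through the end of December 2021, with the
#' last analysis day as the profile-age anchor.
#'
#' @param start_date,end_date Window bounds (anything `as.Date()` accepts).
#' @param reference_date Profile-age anchor date; defaults to `end_date`.
#' @return An object of class `osa_window`: a list with `start_date`,
#'   `end_date` and `reference_date` as `Date`s.
#' @examples
#' analysis_window("2019-12-01", "2021-12-31")
#' @export
analysis_window <- function(start_date = "2019-12-01",
                            end_date = "2021-12-31",
                            reference_date = end_date) {
  w <- list(start_date = as.Date(start_date),
            end_date = as.Date(end_date),
            reference_date = as.Date(reference_date))
  if (is.na(w$start_date) || is.na(w$end_date) || is.na(w$reference_date)) {
    stop("analysis_window: dates must be parseable as dates", call. = FALSE)
  }
  if (w$start_date > w$end_date) {
    stop("analysis_window: start_date must not be after end_date", call. = FALSE)
  }
  structure(w, class = "osa_window")
}

#' @export
print.osa_window <- function(x, ...) {
  cat(sprintf("<osa_window> %s .. %s (profile-age reference %s)\n",
              x$start_date, x$end_date, x$reference_date))
  invisible(x)
}

tweet_count_fields <- c("like_count", "reply_count", "retweet_count", "quote_count")

# shared invariant checks for a canonical tweet table
validate_tweets <- function(tweets) {
  for (f in tweet_count_fields) {
    bad <- which(is.na(tweets[[f]]) | tweets[[f]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("invalid tweet record %d: field '%s' must be a non-negative count (got %s)",
                   bad[1], f, as.character(tweets[[f]][bad[1]])), call. = FALSE)
    }
  }
  dup <- duplicated(tweets$tweet_id)
  if (any(dup)) {
    stop(sprintf("duplicate tweet_id within corpus: '%s'", tweets$tweet_id[which(dup)[1]]),
         call. = FALSE)
  }
  invisible(tweets)
}

as_tweet_tibble <- function(tweet_id, author_handle, created_at, text,
                            like_count, reply_count, retweet_count, quote_count,
                            lang = NA_character_) {
  tibble::tibble(
    tweet_id = as.character(tweet_id),
    author_handle = as.character(author_handle),
    created_at = created_at,
    text = as.character(text),
    like_count = as.integer(like_count),
    reply_count = as.integer(reply_count),
    retweet_count = as.integer(retweet_count),
    quote_count = as.integer(quote_count),
    lang = as.character(lang)
  )
}

empty_tweet_tibble <- function() {
  as_tweet_tibble(character(), character(), as.POSIXct(character(), tz = "UTC"),
                  character(), integer(), integer(), integer(), integer(),
                  character())
}

#' Read tweet records
#'
#' Parses tweets from one of two dialects: `api_v2_jsonl` (JSON Lines using
#' Twitter API v2 field names, with engagement counts nested under
#' `public_metrics`) or `flat_csv` (one row per tweet with the counts as
#' plain columns). Every record is validated: the four public engagement
#' counts must be non-negative and `tweet_id` must be unique within the file.
#'
#' @param path Path to the input file.
#' @param dialect `"api_v2_jsonl"` or `"flat_csv"`.
#' @param window Optional [analysis_window()]; when supplied, a logical
#'   `in_window` column flags records inside the window. Out-of-window
#'   records are retained, never dropped.
#' @return A tibble with columns `tweet_id`, `author_handle`, `created_at`
#'   (POSIXct, UTC), `text`, `like_count`, `reply_count`, `retweet_count`,
#'   `quote_count`, `lang`, and `in_window` when a window was given.
#' @seealso [write_tweets()], [read_roster()]
#' @export
read_tweets <- function(path, dialect = c("api_v2_jsonl", "flat_csv"),
                        window = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("tweet file not found: '%s'", path), call. = FALSE)
  }
  tweets <- switch(dialect,
    api_v2_jsonl = read_tweets_jsonl(path),
    flat_csv = read_tweets_csv(path)
  )
  if (nrow(tweets) == 0) {
    warning(sprintf("no tweet records in '%s'", path), call. = FALSE)
  }
  validate_tweets(tweets)
  if (!is.null(window)) {
    stopifnot(inherits(window, "osa_window"))
    d <- as.Date(tweets$created_at, tz = "UTC")
    tweets$in_window <- d >= window$start_date & d <= window$end_date
  }
  tweets
}

read_tweets_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) return(empty_tweet_tibble())
  recs <- vector("list", length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    obj <- tryCatch(jsonlite::fromJSON(lines[ln]),
                    error = function(e) {
                      stop(sprintf("malformed JSON on line %d of '%s': %s",
                                   ln, path, conditionMessage(e)), call. = FALSE)
                    })
    pm <- obj$public_metrics
    missing_pm <- setdiff(tweet_count_fields, names(pm))
    if (is.null(pm) || length(missing_pm) > 0) {
      stop(sprintf("line %d of '%s': public_metrics missing field(s): %s",
                   ln, path,
                   paste(if (is.null(pm)) tweet_count_fields else missing_pm,
                         collapse = ", ")), call. = FALSE)
    }
    if (is.null(obj$text) || is.null(obj$created_at)) {
      stop(sprintf("line %d of '%s': required field 'text' or 'created_at' missing",
                   ln, path), call. = FALSE)
    }
    recs[[i]] <- tibble::tibble(
      tweet_id = as.character(obj$id %||% obj$tweet_id %||% as.character(ln)),
      author_handle = as.character(obj$author_handle %||% obj$username %||%
                                     obj$author_id %||% NA_character_),
      created_at_raw = as.character(obj$created_at),
      text = as.character(obj$text),
      like_count = as.integer(pm$like_count),
      reply_count = as.integer(pm$reply_count),
      retweet_count = as.integer(pm$retweet_count),
      quote_count = as.integer(pm$quote_count),
      lang = as.character(obj$lang %||% NA_character_)
    )
  }
  out <- dplyr::bind_rows(recs)
  out$created_at <- parse_rfc3339(out$created_at_raw)
  out$created_at_raw <- NULL
  dplyr::relocate(out, "created_at", .after = "author_handle")
}

flat_csv_cols <- c("tweet_id", "author_handle", "created_at", "text",
                   "like_count", "reply_count", "retweet_count", "quote_count")

read_tweets_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    tweet_id = readr::col_character(),
    author_handle = readr::col_character(),
    created_at = readr::col_character(),
    text = readr::col_character(),
    like_count = readr::col_integer(),
    reply_count = readr::col_integer(),
    retweet_count = readr::col_integer(),
    quote_count = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(flat_csv_cols, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("flat_csv '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_tweet_tibble())
  as_tweet_tibble(raw$tweet_id, raw$author_handle, parse_rfc3339(raw$created_at),
                  raw$text, raw$like_count, raw$reply_count, raw$retweet_count,
                  raw$quote_count, raw$lang %||% NA_character_)
}

#' Write tweet records
#'
#' Serializes a canonical tweet table to either dialect read by
#' [read_tweets()]. Timestamps are written as RFC 3339 in UTC, so a flat-CSV
#' round trip reproduces the records exactly.
#'
#' @param tweets Tweet tibble as returned by [read_tweets()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @param dialect `"api_v2_jsonl"` or `"flat_csv"`.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path, dialect = c("api_v2_jsonl", "flat_csv")) {
  dialect <- match.arg(dialect)
  validate_tweets(tweets)
  if (dialect == "flat_csv") {
    out <- tweets[, intersect(c(flat_csv_cols, "lang"), names(tweets))]
    out$created_at <- format_rfc3339(out$created_at)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(tweets))) {
      obj <- list(
        id = tweets$tweet_id[i],
        author_handle = tweets$author_handle[i],
        created_at = format_rfc3339(tweets$created_at[i]),
        text = tweets$text[i],
        public_metrics = list(
          like_count = tweets$like_count[i],
          reply_count = tweets$reply_count[i],
          retweet_count = tweets$retweet_count[i],
          quote_count = tweets$quote_count[i]
        )
      )
      if (!is.na(tweets$lang[i] %||% NA)) obj$lang <- tweets$lang[i]
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con, useBytes = TRUE)
    }
  }
  invisible(path)
}

#' Read an account roster
#'
#' The roster maps raw Twitter handles to canonical users: some accounts (for
#' example a head of government with both a personal and an office handle)
#' tweet under more than one handle but are analyzed as one user. Exactly one
#' handle per user is flagged `primary`; its profile metrics represent the
#' user (audiences overlap, so follower counts are never summed across
#' handles).
#'
#' @param path CSV with header `handle,user_id,group,country,primary`.
#' @return A tibble with those columns (`primary` as logical).
#' @export
read_roster <- function(path) {
  roster <- readr::read_csv(path, col_types = readr::cols(
    handle = readr::col_character(),
    user_id = readr::col_character(),
    group = readr::col_character(),
    country = readr::col_character(),
    primary = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  validate_roster(roster)
}

validate_roster <- function(roster) {
  need <- c("handle", "user_id", "group", "country", "primary")
  missing <- setdiff(need, names(roster))
  if (length(missing) > 0) {
    stop(sprintf("roster is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(roster$group), USER_GROUPS)
  if (length(bad_group) > 0) {
    stop(sprintf("unknown user group(s) in roster: %s (expected %s)",
                 paste(bad_group, collapse = ", "),
                 paste(USER_GROUPS, collapse = ", ")), call. = FALSE)
  }
  multi <- tapply(roster$user_id, roster$handle, function(u) length(unique(u)))
  if (any(multi > 1)) {
    stop(sprintf("handle '%s' maps to more than one user_id",
                 names(multi)[which(multi > 1)[1]]), call. = FALSE)
  }
  n_primary <- tapply(roster$primary, roster$user_id, sum)
  if (any(n_primary != 1)) {
    stop(sprintf("user '%s' must have exactly one primary handle",
                 names(n_primary)[which(n_primary != 1)[1]]), call. = FALSE)
  }
  tibble::as_tibble(roster)
}

#' Read per-handle account profiles
#'
#' @param path CSV with header `handle,display_name,followers,following,`
#'   `listed_count,total_tweet_count,profile_created_at`.
#' @return A tibble of raw per-handle profiles.
#' @export
read_profiles <- function(path) {
  p <- readr::read_csv(path, col_types = readr::cols(
    handle = readr::col_character(),
    display_name = readr::col_character(),
    followers = readr::col_double(),
    following = readr::col_double(),
    listed_count = readr::col_double(),
    total_tweet_count = readr::col_double(),
    profile_created_at = readr::col_date()
  ), progress = FALSE, show_col_types = FALSE)
  for (f in c("followers", "following", "listed_count", "total_tweet_count")) {
    if (any(is.na(p[[f]]) | p[[f]] < 0)) {
      stop(sprintf("profile field '%s' must be non-negative", f), call. = FALSE)
    }
  }
  tibble::as_tibble(p)
}

#' Merge multiple handles into canonical users
#'
#' Re-keys tweets from raw handles to canonical `user_id`s and collapses
#' per-handle profiles into one profile per user. Tweet streams are unioned
#' across a user's handles; profile metrics (followers, following, listed
#' count, profile age) are taken from the roster-designated primary handle,
#' never summed, because follower audiences of the same person's accounts
#' overlap.
#'
#' @param profiles Per-handle profile tibble ([read_profiles()]).
#' @param tweets Canonical tweet tibble ([read_tweets()]).
#' @param roster Roster tibble ([read_roster()]).
#' @return A list with `profiles` (one row per canonical user, with a
#'   `handles` list-column) and `tweets` (input tweets plus a `user_id`
#'   column).
#' @export
merge_handles <- function(profiles, tweets, roster) {
  roster <- validate_roster(roster)
  orphans <- setdiff(unique(tweets$author_handle), roster$handle)
  if (length(orphans) > 0) {
    stop(sprintf("tweet author handle(s) absent from roster: %s",
                 paste(sort(orphans), collapse = ", ")), call. = FALSE)
  }
  missing_profiles <- setdiff(roster$handle[roster$primary], profiles$handle)
  if (length(missing_profiles) > 0) {
    stop(sprintf("no profile record for primary handle(s): %s",
                 paste(sort(missing_profiles), collapse = ", ")), call. = FALSE)
  }
  tweets$user_id <- roster$user_id[match(tweets$author_handle, roster$handle)]

  primary <- roster[roster$primary, c("handle", "user_id", "group", "country")]
  canon <- dplyr::inner_join(primary, profiles, by = "handle")
  handles_by_user <- split(roster$handle, roster$user_id)
  canon$handles <- unname(handles_by_user[canon$user_id])
  canon <- dplyr::relocate(canon, "user_id", "handles", "display_name",
                           "group", "country")
  canon$handle <- NULL
  list(profiles = tibble::as_tibble(canon), tweets = tweets)
}

#' Extract hashtags and mentions from tweet text
#'
#' Tokens are maximal runs of unicode word characters prefixed by `#`
#' (hashtags) or `@` (mentions); punctuation terminates a token. Tokens are
#' lowercased with the prefix stripped, order of appearance is preserved, and
#' duplicates within one text are kept (so `"#covid19 #COVID19"` yields
#' `"covid19"` twice).
#'
#' @param text Character vector of tweet texts.
#' @return For a single text, a list with character vectors `hashtags` and
#'   `mentions`; for longer input, a tibble with list-columns `hashtags` and
#'   `mentions`, one row per text.
#' @examples
#' extract_entities("Stay safe #COVID19 #covid19 @WHO")
#' @export
extract_entities <- function(text) {
  h <- extract_hashtags(text)
  m <- extract_mentions(text)
  if (length(text) == 1) {
    list(hashtags = h[[1]], mentions = m[[1]])
  } else {
    tibble::tibble(hashtags = h, mentions = m)
  }
}

#' @rdname extract_entities
#' @export
extract_hashtags <- function(text) {
  lapply(stringr::str_extract_all(text, "#\\w+"),
         function(x) stringr::str_to_lower(stringr::str_sub(x, 2)))
}

#' @rdname extract_entities
#' @export
extract_mentions <- function(text) {
  lapply(stringr::str_extract_all(text, "@\\w+"),
         function(x) stringr::str_to_lower(stringr::str_sub(x, 2)))
}

#' Profile age in whole days
#'
#' Days between the profile creation date and the window's reference date,
#' by UTC calendar-date arithmetic. The impact score divides by the square of
#' this quantity, so a zero or negative age is an error.
#'
#' @param profile_created_at Creation date(s) (`Date` or parseable).
#' @param window An [analysis_window()]; its `reference_date` is the anchor.
#' @return Integer vector of positive day counts.
#' @export
profile_age_days <- function(profile_created_at, window) {
  stopifnot(inherits(window, "osa_window"))
  created <- as.Date(profile_created_at)
  age <- as.integer(window$reference_date - created)
  if (any(is.na(age))) stop("unparseable profile creation date", call. = FALSE)
  if (any(age <= 0)) {
    stop(sprintf("profile created on/after the reference date %s (age must be >= 1 day)",
                 window$reference_date), call. = FALSE)
  }
  age
}
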
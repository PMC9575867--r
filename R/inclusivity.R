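LEXICON_CATEGORIES <- c("gender", "age", "culture", "ethnicity", "employment")

#' Load a community-keyword lexicon
#'
#' Community keywords span five categories -- gender, age, cultural
#' inference, ethnicity and employment sector -- and may be country-specific
#' (`country = "all"` applies everywhere). Keywords are lowercased and
#' duplicate `(keyword, country)` rows are dropped with a warning. The
#' bundled starter lexicon ([default_community_lexicon()]) is a synthetic
#' stand-in of ~100 category-balanced English terms with `country = "all"`;
#' studies of a specific country should supply their own lists.
#'
#' @param path CSV with header `keyword,category,country`, or a JSON array of
#'   objects with those fields.
#' @return A tibble `keyword, category, country`.
#' @export
load_lexicon <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lex <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    lex <- readr::read_csv(path, col_types = readr::cols(
      keyword = readr::col_character(),
      category = readr::col_character(),
      country = readr::col_character()
    ), progress = FALSE, show_col_types = FALSE)
  }
  need <- c("keyword", "category", "country")
  missing <- setdiff(need, names(lex))
  if (length(missing) > 0) {
    stop(sprintf("lexicon missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(lex) == 0) stop("lexicon is empty", call. = FALSE)
  bad <- setdiff(unique(lex$category), LEXICON_CATEGORIES)
  if (length(bad) > 0) {
    stop(sprintf("unknown lexicon category: %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(LEXICON_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  lex$keyword <- stringr::str_to_lower(lex$keyword)
  dup <- duplicated(lex[, c("keyword", "country")])
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate (keyword, country) lexicon row(s)",
                    sum(dup)), call. = FALSE)
    lex <- lex[!dup, ]
  }
  tibble::as_tibble(lex)
}

#' @rdname load_lexicon
#' @export
default_community_lexicon <- function() {
  load_lexicon(system.file("extdata", "community_lexicon.csv",
                           package = "osascore", mustWork = TRUE))
}

# one boundary-anchored alternation over all keywords; phrases stay contiguous
lexicon_pattern <- function(keywords) {
  esc <- stringr::str_replace_all(keywords, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
  stringr::regex(paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b"),
                 ignore_case = TRUE)
}

#' Flag tweets that mention any community keyword
#'
#' Matching is case-insensitive and whole-word (unicode word boundaries);
#' multi-word keywords must appear as contiguous phrases. `"nurse"` does not
#' match `"nurses"` -- stem variants must be listed explicitly.
#'
#' @param texts Character vector of tweet texts.
#' @param lexicon Lexicon tibble ([load_lexicon()]).
#' @param country Restrict to entries for this country plus `"all"`.
#' @return Logical vector: does each text contain at least one keyword?
#' @export
mentions_community <- function(texts, lexicon, country = "all") {
  lex <- lexicon[lexicon$country %in% unique(c(country, "all")), ]
  if (nrow(lex) == 0) return(rep(FALSE, length(texts)))
  stringr::str_detect(texts, lexicon_pattern(lex$keyword))
}

#' Count community-mention tweets for one user
#'
#' A tweet counts at most once no matter how many keywords it contains: the
#' statistic is the number of tweets referring to any community, not the
#' number of keyword occurrences.
#'
#' @inheritParams mentions_community
#' @return A list with `community_mention_tweets` and `total_tweets`.
#' @export
count_community_mentions <- function(texts, lexicon, country = "all") {
  if (length(texts) == 0) {
    stop("count_community_mentions: empty tweet list", call. = FALSE)
  }
  list(community_mention_tweets = sum(mentions_community(texts, lexicon, country)),
       total_tweets = length(texts))
}

#' Inclusivity-and-diversity strength
#'
#' The fraction of a user's tweets that mention at least one community
#' keyword. A user who never refers to any community receives the sentinel
#' `1e-6` rather than zero, so the multiplicative composite never collapses
#' to exactly zero for that reason alone.
#'
#' @param community_mention_tweets,total_tweets Counts (vectorized).
#' @return Numeric strength(s) in `{1e-6}` union `(0, 1]`.
#' @examples
#' id_strength(3, 12)  # 0.25
#' id_strength(0, 50)  # 1e-6
#' @export
id_strength <- function(community_mention_tweets, total_tweets) {
  if (any(total_tweets < 1)) {
    stop("id_strength requires total_tweets >= 1", call. = FALSE)
  }
  if (any(community_mention_tweets < 0 | community_mention_tweets > total_tweets)) {
    stop("community_mention_tweets must lie in [0, total_tweets]", call. = FALSE)
  }
  ifelse(community_mention_tweets == 0, 1e-6,
         community_mention_tweets / total_tweets)
}

#' Per-user inclusivity summary and strength
#'
#' @param tweets Tweet tibble with `user_id` and `text` columns; an optional
#'   `country` column on `profiles` restricts country-specific keywords.
#' @param lexicon Lexicon tibble.
#' @param countries Optional named character vector `user_id -> country`.
#' @return A tibble `user_id, community_mention_tweets, total_tweets,
#'   id_strength`.
#' @export
user_inclusivity <- function(tweets, lexicon, countries = NULL) {
  per_user <- split(tweets$text, tweets$user_id)
  rows <- lapply(names(per_user), function(uid) {
    ctry <- if (is.null(countries)) "all" else (countries[[uid]] %||% "all")
    cm <- count_community_mentions(per_user[[uid]], lexicon, ctry)
    tibble::tibble(user_id = uid,
                   community_mention_tweets = cm$community_mention_tweets,
                   total_tweets = cm$total_tweets)
  })
  out <- dplyr::bind_rows(rows)
  out$id_strength <- id_strength(out$community_mention_tweets, out$total_tweets)
  out
}
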
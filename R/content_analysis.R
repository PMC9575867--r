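count_tokens <- function(token_lists, per_tweet_unique = FALSE) {
  if (per_tweet_unique) token_lists <- lapply(token_lists, unique)
  tokens <- unlist(token_lists, use.names = FALSE)
  if (length(tokens) == 0) {
    return(tibble::tibble(token = character(), count = integer()))
  }
  tab <- table(tokens)
  out <- tibble::tibble(token = names(tab), count = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$count), .data$token)
}

#' Top-k hashtag frequency table
#'
#' Counts hashtag usage over a tweet corpus via [extract_entities()] and
#' returns the `k` most frequent, ties broken lexicographically. By default
#' every occurrence counts, so a tweet containing the same hashtag twice
#' contributes two (usage frequency); set `per_tweet_unique = TRUE` to count
#' tweet presence instead.
#'
#' @param tweets Tweet tibble (only `text` is used).
#' @param k Rows to keep (default 10, the conventional report size).
#' @param per_tweet_unique Count each token at most once per tweet?
#' @return A tibble `token, count, rank`, descending by count; empty when the
#'   corpus has no hashtags.
#' @export
top_hashtags <- function(tweets, k = 10, per_tweet_unique = FALSE) {
  if (k < 1) stop("top_hashtags: k must be >= 1", call. = FALSE)
  tab <- count_tokens(extract_hashtags(tweets$text), per_tweet_unique)
  add_rank(head(tab, k))
}

#' Top-k mention frequency table
#'
#' As [top_hashtags()], over `@`-mention tokens.
#'
#' @inheritParams top_hashtags
#' @return A tibble `token, count, rank`.
#' @export
top_mentions <- function(tweets, k = 10, per_tweet_unique = FALSE) {
  if (k < 1) stop("top_mentions: k must be >= 1", call. = FALSE)
  tab <- count_tokens(extract_mentions(tweets$text), per_tweet_unique)
  add_rank(head(tab, k))
}

add_rank <- function(tab) {
  tab$rank <- seq_len(nrow(tab))
  tab
}

#' Frequency tables per user group
#'
#' @param tweets Tweet tibble with a `user_id` column.
#' @param roster Roster tibble mapping users to groups.
#' @param k Rows per table.
#' @return A tibble `scope, kind, token, count, rank` stacking per-group
#'   hashtag and mention tables.
#' @export
group_content_tables <- function(tweets, roster, k = 10) {
  group_of <- setNames(roster$group, roster$user_id)
  tweets$group <- unname(group_of[tweets$user_id])
  rows <- lapply(split(tweets, tweets$group), function(tw) {
    dplyr::bind_rows(
      dplyr::mutate(top_hashtags(tw, k), scope = tw$group[1], kind = "hashtag"),
      dplyr::mutate(top_mentions(tw, k), scope = tw$group[1], kind = "mention")
    )
  })
  dplyr::relocate(dplyr::bind_rows(rows), "scope", "kind")
}
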
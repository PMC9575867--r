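SENTIMENT_LABELS <- c("negative", "neutral", "positive")

#' Read a signed sentiment lexicon
#'
#' @param path Two-column CSV `term,polarity` with polarity in \{-1, +1\}.
#' @return A tibble with lowercase `term` and integer `polarity`.
#' @export
read_sentiment_lexicon <- function(path) {
  lex <- readr::read_csv(path, col_types = readr::cols(
    term = readr::col_character(),
    polarity = readr::col_integer()
  ), progress = FALSE, show_col_types = FALSE)
  if (!all(lex$polarity %in% c(-1L, 1L))) {
    stop("sentiment lexicon polarity must be -1 or +1", call. = FALSE)
  }
  lex$term <- stringr::str_to_lower(lex$term)
  if (anyDuplicated(lex$term)) {
    stop("duplicate term in sentiment lexicon", call. = FALSE)
  }
  lex
}

#' @rdname read_sentiment_lexicon
#' @export
default_sentiment_lexicon <- function() {
  read_sentiment_lexicon(system.file("extdata", "sentiment_lexicon.csv",
                                     package = "osascore", mustWork = TRUE))
}

#' Deterministic signed-lexicon sentiment classifier
#'
#' The bundled fallback for the pluggable classifier interface: each text is
#' scored as (number of positive-lexicon word occurrences) minus (number of
#' negative-lexicon word occurrences), on lowercased unicode word tokens.
#' A positive score maps to `"positive"`, negative to `"negative"`, zero
#' (including texts with no lexicon hits at all) to `"neutral"`. Transformer
#' or other model-based classifiers can be plugged in anywhere a `classifier`
#' argument is accepted: any function mapping a character vector to an
#' equal-length vector of the three labels qualifies.
#'
#' @param lexicon A lexicon tibble ([read_sentiment_lexicon()]).
#' @return A function `character vector -> label vector`.
#' @examples
#' clf <- lexicon_classifier()
#' clf(c("a hopeful milestone", "tragic loss", "daily update"))
#' @export
lexicon_classifier <- function(lexicon = default_sentiment_lexicon()) {
  polarity <- setNames(as.integer(lexicon$polarity), lexicon$term)
  function(texts) {
    tokens <- stringr::str_extract_all(stringr::str_to_lower(texts), "\\w+")
    score <- vapply(tokens, function(tk) {
      sum(polarity[tk], na.rm = TRUE)
    }, numeric(1))
    SENTIMENT_LABELS[sign(score) + 2L]
  }
}

#' Classify tweet texts into three sentiment classes
#'
#' Thin validation wrapper around a pluggable classifier: checks that the
#' classifier returns exactly one label per text and only labels from
#' \{negative, neutral, positive\}.
#'
#' @param texts Character vector.
#' @param classifier A classifier function; defaults to the bundled
#'   [lexicon_classifier()].
#' @return Character vector of labels, aligned with `texts`.
#' @export
classify_sentiment <- function(texts, classifier = lexicon_classifier()) {
  labels <- classifier(texts)
  if (length(labels) != length(texts)) {
    stop(sprintf("classifier returned %d label(s) for %d text(s)",
                 length(labels), length(texts)), call. = FALSE)
  }
  bad <- setdiff(unique(labels), SENTIMENT_LABELS)
  if (length(bad) > 0) {
    stop(sprintf("classifier returned out-of-vocabulary label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  labels
}

#' Per-user sentiment label counts
#'
#' @param user_id Character vector, one entry per tweet.
#' @param labels Sentiment labels aligned with `user_id`.
#' @return A tibble `user_id, n_negative, n_neutral, n_positive, total`.
#' @export
sentiment_summary <- function(user_id, labels) {
  stopifnot(length(user_id) == length(labels))
  df <- tibble::tibble(user_id = user_id,
                       label = factor(labels, levels = SENTIMENT_LABELS))
  out <- df |>
    dplyr::count(.data$user_id, .data$label, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(n_negative = "negative", n_neutral = "neutral",
                  n_positive = "positive")
  out$total <- out$n_negative + out$n_neutral + out$n_positive
  out[out$total >= 1L, ]
}

#' Sentiment strength of a user
#'
#' The signed majority-class statistic: if the most frequent class over the
#' user's tweets is neutral the strength is the sentinel `1e-6`; if positive,
#' it is the fraction of positive tweets; if negative, minus the fraction of
#' negative tweets. Ties for the majority (including a positive/negative
#' tie) resolve to neutral, the most conservative reading, since the sign
#' would otherwise be arbitrary.
#'
#' @param n_negative,n_neutral,n_positive Label counts (vectorized).
#' @return Numeric strength(s) in `[-1, 1]`.
#' @examples
#' sentiment_strength(3, 1, 6)  # 0.6
#' sentiment_strength(3, 6, 1)  # 1e-6
#' @export
sentiment_strength <- function(n_negative, n_neutral, n_positive) {
  counts <- cbind(n_negative, n_neutral, n_positive)
  if (any(counts < 0)) stop("label counts must be non-negative", call. = FALSE)
  total <- rowSums(counts)
  if (any(total < 1)) stop("sentiment summary requires total >= 1 tweet", call. = FALSE)
  top <- pmax(counts[, 1], counts[, 2], counts[, 3])
  n_top <- (counts[, 1] == top) + (counts[, 2] == top) + (counts[, 3] == top)
  majority <- ifelse(n_top > 1, "neutral",
                     SENTIMENT_LABELS[max.col(counts)])
  unname(ifelse(majority == "neutral", 1e-6,
                ifelse(majority == "positive", counts[, 3] / total,
                       -counts[, 1] / total)))
}

#' Per-user sentiment strength from classified tweets
#'
#' Two aggregation modes are provided. `"window"` (the default) pools all of
#' a user's tweets over the analysis window into one label count and applies
#' [sentiment_strength()] once. `"daily_majority"` first reduces each active
#' day to its majority label (ties to neutral), then applies the statistic to
#' the day-level labels; this reading weighs every active day equally
#' regardless of tweet volume.
#'
#' @param tweets Tweet tibble with a `user_id` column.
#' @param labels Sentiment labels aligned with `tweets` rows.
#' @param mode `"window"` or `"daily_majority"`.
#' @return A tibble `user_id, n_negative, n_neutral, n_positive, total,
#'   senti_strength`.
#' @export
user_sentiment <- function(tweets, labels, mode = c("window", "daily_majority")) {
  mode <- match.arg(mode)
  if (mode == "window") {
    s <- sentiment_summary(tweets$user_id, labels)
  } else {
    day_df <- tibble::tibble(user_id = tweets$user_id,
                             date = as.Date(tweets$created_at, tz = "UTC"),
                             label = labels)
    day_labels <- day_df |>
      dplyr::group_by(.data$user_id, .data$date) |>
      dplyr::summarise(label = majority_label(.data$label), .groups = "drop")
    s <- sentiment_summary(day_labels$user_id, day_labels$label)
  }
  s$senti_strength <- sentiment_strength(s$n_negative, s$n_neutral, s$n_positive)
  s
}

majority_label <- function(labels) {
  n <- tabulate(factor(labels, levels = SENTIMENT_LABELS), nbins = 3L)
  if (sum(n == max(n)) > 1) "neutral" else SENTIMENT_LABELS[which.max(n)]
}
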
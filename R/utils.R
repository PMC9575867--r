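#' @importFrom rlang %||% .data
#' @importFrom stats rnbinom rpois rbinom runif sd setNames
#' @importFrom utils head
NULL

# canonical user-group labels used throughout
USER_GROUPS <- c("leader", "health_org")

# parse RFC 3339 / ISO 8601 timestamps into POSIXct (UTC)
parse_rfc3339 <- function(x) {
  out <- readr::parse_datetime(as.character(x))
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    stop(sprintf("unparseable RFC 3339 timestamp at position %d: '%s'",
                 bad[1], x[bad[1]]), call. = FALSE)
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_rfc3339 <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}
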
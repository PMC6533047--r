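#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

LOG_COLUMNS <- c("user_id", "timestamp", "query_text", "clicked_url")
TS_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

#' Format instants as ISO-8601 UTC strings
#' @param x a POSIXct vector.
#' @return character vector like `"2017-07-01T12:34:56Z"`.
#' @export
format_instant <- function(x) {
  format(x, TS_FORMAT, tz = "UTC")
}

#' Parse ISO-8601 UTC strings to instants
#' @param x character vector like `"2017-07-01T12:34:56Z"` (a bare date is
#'   taken as midnight UTC).
#' @return POSIXct vector in UTC; unparseable elements are `NA`.
#' @export
parse_instant <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}Z?$", x)
  if (any(full)) {
    y <- sub("Z$", "", sub("T", " ", x[full]))
    out[full] <- as.POSIXct(y, tz = "UTC")
  }
  bare <- !full & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(bare)) {
    out[bare] <- as.POSIXct(x[bare], tz = "UTC")
  }
  out
}

#' Construct a search log
#'
#' A search log couples a table of timestamped query events with the half-open
#' observation span `[span_start, span_end)` they were collected in. One event
#' is one search action by one anonymous user: the user identifier, the
#' instant of the query, its free text, and optionally the URL the user
#' clicked in response.
#'
#' @param events data frame with columns `user_id` (character),
#'   `timestamp` (POSIXct, UTC), `query_text` (character, non-empty after
#'   trimming) and `clicked_url` (character, `NA` when no click).
#' @param span_start,span_end observation span bounds (POSIXct or ISO-8601
#'   strings); every event timestamp must lie in `[span_start, span_end)`.
#' @return an object of class `search_log`: a list with elements `events`
#'   (tibble), `span_start` and `span_end`.
#' @export
search_log <- function(events, span_start, span_end) {
  span_start <- as_instant_scalar(span_start, "span_start")
  span_end <- as_instant_scalar(span_end, "span_end")
  if (!span_end > span_start) {
    stop("span_end must be after span_start", call. = FALSE)
  }
  events <- as_tibble(events)
  missing_cols <- setdiff(LOG_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- events[LOG_COLUMNS]
  events$user_id <- as.character(events$user_id)
  events$query_text <- as.character(events$query_text)
  events$clicked_url <- as.character(events$clicked_url)
  if (!inherits(events$timestamp, "POSIXct")) {
    events$timestamp <- parse_instant(events$timestamp)
  }
  attr(events$timestamp, "tzone") <- "UTC"
  if (nrow(events) > 0) {
    if (anyNA(events$user_id) || any(events$user_id == "")) {
      stop("user_id must be non-missing and non-empty", call. = FALSE)
    }
    if (anyNA(events$timestamp)) {
      stop("timestamps must be non-missing and parseable", call. = FALSE)
    }
    # validate on unique strings: logs repeat a small vocabulary
    uq_query <- unique(events$query_text)
    qt <- trimws(uq_query)
    if (anyNA(qt) || any(qt == "")) {
      stop("query_text must be non-empty after whitespace trimming",
           call. = FALSE)
    }
    uq_url <- unique(events$clicked_url)
    bad_chars <- any(grepl("[\t\n\r]", unique(events$user_id))) ||
      any(grepl("[\t\n\r]", uq_query)) ||
      any(grepl("[\t\n\r]", uq_url[!is.na(uq_url)]))
    if (bad_chars) {
      stop("fields must not contain tab or newline characters", call. = FALSE)
    }
    out_of_span <- events$timestamp < span_start | events$timestamp >= span_end
    if (any(out_of_span)) {
      stop(sum(out_of_span), " event timestamp(s) outside [span_start, span_end)",
           call. = FALSE)
    }
  }
  structure(
    list(events = events, span_start = span_start, span_end = span_end),
    class = "search_log"
  )
}

as_instant_scalar <- function(x, what) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
  } else {
    x <- parse_instant(x)
  }
  if (length(x) != 1 || is.na(x)) {
    stop(what, " must be a single valid instant", call. = FALSE)
  }
  x
}

#' @export
print.search_log <- function(x, ...) {
  cat(sprintf(
    "<search_log> %d events, %d users, span [%s, %s)\n",
    nrow(x$events), dplyr::n_distinct(x$events$user_id),
    format_instant(x$span_start), format_instant(x$span_end)
  ))
  invisible(x)
}

#' Number of events in a search log
#' @param log a `search_log`.
#' @return integer event count.
#' @export
n_events <- function(log) {
  stopifnot(inherits(log, "search_log"))
  nrow(log$events)
}

#' Read a tab-separated query log
#'
#' The on-disk format is four tab-separated columns with header
#' `user_id<TAB>timestamp<TAB>query_text<TAB>clicked_url`, timestamps in
#' ISO-8601 UTC, and an empty `clicked_url` field meaning "no click". An
#' optional first line `#span<TAB>start<TAB>end` records the observation
#' span; without it the span is inferred from the data (floor/ceiling to the
#' enclosing whole days). Files ending in `.gz` are decompressed
#' transparently.
#'
#' @param path path to the log file.
#' @return a [search_log()].
#' @export
read_query_log <- function(path) {
  if (!file.exists(path)) {
    stop("log file does not exist: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0 || all(lines == "")) {
    stop("empty log file: ", path, call. = FALSE)
  }
  span_start <- span_end <- NULL
  offset <- 0L
  if (startsWith(lines[1], "#span\t")) {
    parts <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop("malformed #span line in ", path, call. = FALSE)
    }
    span_start <- parse_instant(parts[2])
    span_end <- parse_instant(parts[3])
    if (is.na(span_start) || is.na(span_end)) {
      stop("unparseable span instants in ", path, call. = FALSE)
    }
    offset <- 1L
  }
  header <- strsplit(lines[offset + 1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, LOG_COLUMNS)) {
    stop("log header must name the four columns ",
         paste(LOG_COLUMNS, collapse = ", "), call. = FALSE)
  }
  data_lines <- lines[seq_along(lines) > offset + 1L]
  data_lines <- data_lines[data_lines != ""]
  if (length(data_lines) == 0) {
    events <- tibble(
      user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      query_text = character(), clicked_url = character()
    )
  } else {
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    # a trailing empty clicked_url field is dropped by strsplit
    bad_n <- nf != 4L & nf != 3L
    line_no <- seq_along(data_lines) + offset + 1L
    if (any(bad_n)) {
      stop("malformed row(s) at line(s) ",
           paste(line_no[bad_n], collapse = ", "),
           ": expected 4 tab-separated fields", call. = FALSE)
    }
    m <- matrix("", nrow = length(fields), ncol = 4)
    m[nf == 4L, ] <- do.call(rbind, fields[nf == 4L])
    if (any(nf == 3L)) {
      m[nf == 3L, 1:3] <- do.call(rbind, fields[nf == 3L])
    }
    ts <- parse_instant(m[, 2])
    if (anyNA(ts)) {
      stop("unparseable timestamp at line(s) ",
           paste(line_no[is.na(ts)], collapse = ", "), call. = FALSE)
    }
    empty_q <- trimws(m[, 3]) == ""
    if (any(empty_q)) {
      stop("empty query_text at line(s) ",
           paste(line_no[empty_q], collapse = ", "), call. = FALSE)
    }
    events <- tibble(
      user_id = m[, 1], timestamp = ts, query_text = m[, 3],
      clicked_url = ifelse(m[, 4] == "", NA_character_, m[, 4])
    )
  }
  if (is.null(span_start)) {
    if (nrow(events) == 0) {
      stop("cannot infer span from a log with no events; ",
           "write logs with write_query_log() to preserve the span",
           call. = FALSE)
    }
    day <- 86400
    span_start <- as.POSIXct(floor(as.numeric(min(events$timestamp)) / day) * day,
                             tz = "UTC", origin = "1970-01-01")
    span_end <- as.POSIXct(ceiling((as.numeric(max(events$timestamp)) + 1) / day) * day,
                           tz = "UTC", origin = "1970-01-01")
  }
  search_log(events, span_start, span_end)
}

#' Write a query log to a tab-separated file
#'
#' Inverse of [read_query_log()]: writing then reading gives back a log with
#' field-wise identical events and the same span (timestamps are serialized
#' at second resolution). A `.gz` extension triggers gzip compression.
#'
#' @param log a [search_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_query_log <- function(log, path) {
  stopifnot(inherits(log, "search_log"))
  ev <- log$events
  lines <- c(
    paste("#span", format_instant(log$span_start), format_instant(log$span_end),
          sep = "\t"),
    paste(LOG_COLUMNS, collapse = "\t")
  )
  if (nrow(ev) > 0) {
    lines <- c(lines, paste(
      ev$user_id, format_instant(ev$timestamp), ev$query_text,
      ifelse(is.na(ev$clicked_url), "", ev$clicked_url),
      sep = "\t"
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Per-user event histories
#'
#' Splits a log into per-user histories: the returned table contains every
#' event of the log, ordered by `user_id` and, within a user, ascending in
#' time with ties kept in input order (deterministic pipelines need a stable
#' sort). This long-format table is the collection of user histories used by
#' the downstream screens.
#'
#' @param log a [search_log()].
#' @return tibble with the four log columns, sorted by `(user_id, timestamp)`.
#' @export
user_histories <- function(log) {
  stopifnot(inherits(log, "search_log"))
  ev <- log$events
  ord <- order(ev$user_id, ev$timestamp)  # order() is stable
  ev[ord, , drop = FALSE]
}
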
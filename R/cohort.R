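#' Read a labeled seed-URL list
#'
#' Two-column tab-separated file with header `url<TAB>label`, label `AA` or
#' `NA` (the literal program label, not a missing value).
#'
#' @param path file path.
#' @return tibble with columns `url`, `label`.
#' @export
read_seed_urls <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = NULL, quote = "")
  if (!all(c("url", "label") %in% names(tab))) {
    stop("seed-URL file must have columns url and label", call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop("empty seed-URL file: ", path, call. = FALSE)
  }
  if (!all(tab$label %in% c("AA", "NA"))) {
    stop("seed-URL labels must be AA or NA", call. = FALSE)
  }
  tibble(url = tab$url, label = tab$label)
}

has_token <- function(text, token) {
  grepl(pad(normalize_text(token)), pad(normalize_text(text)), fixed = TRUE)
}

#' Discover 12-step seed queries from click behavior
#'
#' A seed query is a normalized query string issued, with a click through to
#' at least one known 12-step resource page, by at least `min_users` distinct
#' users. Each retained query is labeled `AA` or `NA` by the majority label of
#' its clicked seed URLs (`BOTH` on a tie) and flagged as a meeting query when
#' it contains the token "meeting".
#'
#' @param log a [search_log()].
#' @param seed_urls tibble from [read_seed_urls()] (non-empty).
#' @param min_users retention threshold on distinct users; the published
#'   analysis used 50, but smaller synthetic logs need smaller values.
#' @return tibble with columns `query_text` (normalized), `label`, `n_users`,
#'   `is_meeting`, sorted by descending `n_users`.
#' @export
discover_seed_queries <- function(log, seed_urls, min_users = 50) {
  stopifnot(inherits(log, "search_log"))
  seed_urls <- as_tibble(seed_urls)
  if (nrow(seed_urls) == 0) {
    stop("seed_urls must be non-empty", call. = FALSE)
  }
  ev <- log$events
  m <- match(ev$clicked_url, seed_urls$url)
  clicked <- !is.na(m)
  if (!any(clicked)) {
    return(tibble(query_text = character(), label = character(),
                  n_users = integer(), is_meeting = logical()))
  }
  hits <- tibble(
    query_text = normalize_text(ev$query_text[clicked]),
    user_id = ev$user_id[clicked],
    label = seed_urls$label[m[clicked]]
  )
  agg <- dplyr::summarise(
    dplyr::group_by(hits, .data$query_text),
    n_users = dplyr::n_distinct(.data$user_id),
    n_aa = sum(.data$label == "AA"),
    n_na = sum(.data$label == "NA"),
    .groups = "drop"
  )
  agg <- agg[agg$n_users >= min_users, , drop = FALSE]
  out <- tibble(
    query_text = agg$query_text,
    label = ifelse(agg$n_aa > agg$n_na, "AA",
                   ifelse(agg$n_na > agg$n_aa, "NA", "BOTH")),
    n_users = agg$n_users,
    is_meeting = has_token(agg$query_text, "meeting")
  )
  out[order(-out$n_users, out$query_text), , drop = FALSE]
}

seed_event_table <- function(log, seeds) {
  ev <- log$events
  norm <- normalize_text(ev$query_text)
  is_seed <- norm %in% seeds$query_text
  tibble(
    user_id = ev$user_id[is_seed],
    timestamp = ev$timestamp[is_seed],
    query_text = norm[is_seed],
    order = which(is_seed)
  )
}

#' Partition users into target, comparison and excluded
#'
#' Target users are those whose first seed-query event falls inside the index
#' window (the final month of the span) with no seed queries before it; their
#' `index_time` is that first seed query's timestamp. Users with any seed
#' query before the index window are excluded from both populations (prior
#' treatment seekers would contaminate the comparison baseline). Everyone
#' else is the comparison population.
#'
#' @param log a [search_log()].
#' @param seeds seed-query table from [discover_seed_queries()].
#' @param index_window optional length-2 `(start, end)`; defaults to the
#'   final calendar month of the log span. Must lie within the span.
#' @return tibble with one row per distinct user: `user_id`, `role`
#'   (`target` / `comparison` / `excluded`), `group`, `meeting_subsample`
#'   (both `NA` until [assign_subgroups()]), `index_time`.
#' @export
identify_cohort <- function(log, seeds, index_window = NULL) {
  stopifnot(inherits(log, "search_log"))
  if (is.null(index_window)) {
    index_window <- c(max(month_floor(log$span_end - 1), log$span_start),
                      log$span_end)
  } else {
    index_window <- as_period(index_window)
  }
  if (index_window[1] < log$span_start || index_window[2] > log$span_end) {
    stop("index_window must lie within the log span", call. = FALSE)
  }
  all_users <- unique(log$events$user_id)
  se <- seed_event_table(log, seeds)
  role <- stats::setNames(rep("comparison", length(all_users)), all_users)
  index_time <- stats::setNames(rep(as.POSIXct(NA, tz = "UTC"),
                                    length(all_users)), all_users)
  if (nrow(se) > 0) {
    se <- se[order(se$user_id, se$timestamp, se$order), ]
    first <- se[!duplicated(se$user_id), ]
    pre_window <- first$timestamp < index_window[1]
    in_window <- first$timestamp >= index_window[1] &
      first$timestamp < index_window[2]
    role[first$user_id[pre_window]] <- "excluded"
    role[first$user_id[in_window]] <- "target"
    index_time[first$user_id[in_window]] <- first$timestamp[in_window]
  }
  tibble(
    user_id = all_users,
    role = unname(role),
    group = NA_character_,
    meeting_subsample = NA,
    index_time = unname(index_time)
  )
}

#' Fill in target subgroups and the meeting subsample flag
#'
#' A target user's subgroup is `AA` when all their index-window seed queries
#' are AA-labeled, `NA` when all are NA-labeled, and `BOTH` otherwise (a
#' tie-labeled seed query counts as both programs). The meeting-subsample
#' flag is true when the user's first seed query is a meeting query.
#'
#' @param assignments output of [identify_cohort()].
#' @param log the same [search_log()].
#' @param seeds the same seed-query table.
#' @return `assignments` with `group` and `meeting_subsample` filled for
#'   target users.
#' @export
assign_subgroups <- function(assignments, log, seeds) {
  targets <- assignments$user_id[assignments$role == "target"]
  if (length(targets) == 0) {
    return(assignments)
  }
  se <- seed_event_table(log, seeds)
  se <- se[se$user_id %in% targets, , drop = FALSE]
  se$label <- seeds$label[match(se$query_text, seeds$query_text)]
  se$is_meeting <- seeds$is_meeting[match(se$query_text, seeds$query_text)]
  idx <- assignments$index_time[match(se$user_id, assignments$user_id)]
  se <- se[se$timestamp >= idx, , drop = FALSE]  # index-window events only
  has_aa <- tapply(se$label %in% c("AA", "BOTH"), se$user_id, any)
  has_na <- tapply(se$label %in% c("NA", "BOTH"), se$user_id, any)
  group <- ifelse(has_aa & has_na, "BOTH", ifelse(has_aa, "AA", "NA"))
  se_first <- se[order(se$user_id, se$timestamp, se$order), ]
  se_first <- se_first[!duplicated(se_first$user_id), ]
  meeting <- stats::setNames(se_first$is_meeting, se_first$user_id)
  at <- match(names(group), assignments$user_id)
  assignments$group[at] <- unname(group)
  assignments$meeting_subsample[at] <-
    unname(meeting[names(group)])
  assignments
}

#' Fraction of seed-query events containing a keyword
#'
#' Among all seed-query events made by the given users, the proportion whose
#' text contains the keyword as a whole token. Used as a contamination audit
#' (e.g. how many treatment-seeking queries mention "alanon", which typically
#' signals family members searching on someone else's behalf).
#'
#' @param log a [search_log()].
#' @param users character vector of user ids (non-empty).
#' @param keyword single token to look for.
#' @param seeds seed-query table from [discover_seed_queries()].
#' @return proportion in `[0, 1]`.
#' @export
keyword_fraction <- function(log, users, keyword, seeds) {
  if (length(users) == 0) {
    stop("users must be non-empty", call. = FALSE)
  }
  se <- seed_event_table(log, seeds)
  se <- se[se$user_id %in% users, , drop = FALSE]
  if (nrow(se) == 0) {
    stop("no seed-query events for the given users: proportion undefined",
         call. = FALSE)
  }
  mean(has_token(se$query_text, keyword))
}

#' Write / read a cohort assignment table
#'
#' Tab-separated with header `user_id, role, group, meeting_subsample,
#' index_time`; missing fields are written empty so the `NA` subgroup label
#' survives the round trip.
#'
#' @param assignments tibble from [identify_cohort()] / [assign_subgroups()].
#' @param path file path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_cohort <- function(assignments, path) {
  out <- assignments
  out$index_time <- ifelse(is.na(out$index_time), "",
                           format_instant(out$index_time))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = NULL, quote = "")
  tibble(
    user_id = tab$user_id,
    role = tab$role,
    group = ifelse(tab$group == "", NA_character_, tab$group),
    meeting_subsample = ifelse(tab$meeting_subsample == "", NA,
                               tab$meeting_subsample == "TRUE"),
    index_time = parse_instant(tab$index_time)
  )
}
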
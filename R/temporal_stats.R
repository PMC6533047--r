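#' Lead-up window specification
#'
#' The 30 days before a user's index time (their first 12-step seed query)
#' are partitioned into three disjoint half-open windows, measured backwards
#' from the index time:
#' * `distal`   = `[-30, -14)` days,
#' * `middle`   = `[-14,  -7)` days,
#' * `proximal` = `[ -7,   0)` days.
#'
#' @return tibble with columns `label`, `start_day`, `end_day` (offsets in
#'   days relative to the index time; half-open `[start_day, end_day)`).
#' @export
window_specs <- function() {
  tibble(
    label = c("distal", "middle", "proximal"),
    start_day = c(-30, -14, -7),
    end_day = c(-14, -7, 0)
  )
}

LEADUP_DAYS <- 30

validate_windows <- function(windows) {
  windows <- as_tibble(windows)
  stopifnot(all(c("label", "start_day", "end_day") %in% names(windows)),
            !anyDuplicated(windows$label),
            all(windows$start_day < windows$end_day))
  w <- windows[order(windows$start_day), ]
  if (nrow(w) > 1 && any(w$end_day[-nrow(w)] > w$start_day[-1])) {
    stop("lead-up windows must be disjoint", call. = FALSE)
  }
  windows
}

as_period <- function(period) {
  if (is.null(period)) return(NULL)
  stopifnot(length(period) == 2)
  lo <- as_instant_scalar(period[[1]], "period start")
  hi <- as_instant_scalar(period[[2]], "period end")
  stopifnot(lo < hi)
  c(lo, hi)
}

#' Person-level probability of querying a symptom
#'
#' Fraction of users (among all users present in `histories`) with at least
#' one query matching the symptom, optionally restricted to a half-open time
#' period. A user counts once no matter how often they repeat the query.
#'
#' @param histories event tibble (log columns), e.g. from [user_histories()];
#'   the denominator is the number of distinct users in it.
#' @param symptom canonical symptom name.
#' @param lexicon a [symptom_lexicon()].
#' @param period optional length-2 vector `(start, end)`; when omitted the
#'   whole history counts.
#' @return proportion in `[0, 1]`.
#' @export
symptom_user_probability <- function(histories, symptom, lexicon,
                                     period = NULL) {
  n_users <- dplyr::n_distinct(histories$user_id)
  if (n_users == 0) {
    stop("histories contain no users", call. = FALSE)
  }
  hits <- symptom_hits(histories, lexicon)
  hits <- hits[hits$symptom == symptom, , drop = FALSE]
  period <- as_period(period)
  if (!is.null(period)) {
    hits <- hits[hits$timestamp >= period[1] & hits$timestamp < period[2], ,
                 drop = FALSE]
  }
  dplyr::n_distinct(hits$user_id) / n_users
}

#' Between-group probability-ratio screen
#'
#' For every lexicon symptom, the person-level probability of querying the
#' symptom in the target population divided by the same probability in the
#' comparison population, ranked from highest to lowest ratio. Symptoms never
#' queried by the comparison population have an undefined ratio and are
#' reported last with `ratio = NA`.
#'
#' @param target_events,comparison_events event tibbles (log columns) for the
#'   two populations; both must be non-empty.
#' @param lexicon a [symptom_lexicon()].
#' @return tibble with columns `symptom`, `p_target`, `p_comparison`, `ratio`,
#'   `rank`, sorted by descending ratio (undefined ratios last).
#' @export
probability_ratio_screen <- function(target_events, comparison_events,
                                     lexicon) {
  n_t <- dplyr::n_distinct(target_events$user_id)
  n_c <- dplyr::n_distinct(comparison_events$user_id)
  if (n_t == 0 || n_c == 0) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  count_users <- function(events) {
    h <- dplyr::distinct(symptom_hits(events, lexicon), .data$user_id,
                         .data$symptom)
    dplyr::count(h, .data$symptom, name = "n_users")
  }
  grid <- tibble(symptom = lexicon_symptoms(lexicon))
  tc <- dplyr::left_join(grid, count_users(target_events), by = "symptom")
  cc <- dplyr::left_join(grid, count_users(comparison_events), by = "symptom")
  out <- tibble(
    symptom = grid$symptom,
    p_target = dplyr::coalesce(tc$n_users, 0L) / n_t,
    p_comparison = dplyr::coalesce(cc$n_users, 0L) / n_c
  )
  out$ratio <- ifelse(out$p_comparison > 0, out$p_target / out$p_comparison,
                      NA_real_)
  defined <- !is.na(out$ratio)
  out <- out[order(!defined, -ifelse(defined, out$ratio, -Inf), out$symptom), ]
  out$rank <- NA_integer_
  out$rank[!is.na(out$ratio)] <- seq_len(sum(!is.na(out$ratio)))
  out
}

# Person-level window / baseline contingency tables for all (symptom, window)
# pairs at once; build_window_table() and temporal_screen() both sit on this.
window_tables_all <- function(target_events, index_times, lexicon,
                              windows = window_specs(), span_start) {
  windows <- validate_windows(windows)
  span_start <- as_instant_scalar(span_start, "span_start")
  index_times <- as_tibble(index_times)
  stopifnot(all(c("user_id", "index_time") %in% names(index_times)),
            !anyDuplicated(index_times$user_id))
  if (anyNA(index_times$index_time)) {
    stop("every target user needs an index_time", call. = FALSE)
  }
  # a user is evaluable when their baseline period [span_start, index - 30d)
  # is non-empty by at least one day
  idx_num <- as.numeric(index_times$index_time)
  evaluable <- idx_num - as.numeric(span_start) >= (LEADUP_DAYS + 1) * DAY
  n_eval <- sum(evaluable)
  n_dropped <- sum(!evaluable)
  if (n_eval == 0) {
    stop("zero evaluable target users (all observed < 31 days before index)",
         call. = FALSE)
  }
  eval_users <- index_times$user_id[evaluable]
  ev <- target_events[target_events$user_id %in% eval_users, , drop = FALSE]
  hits <- symptom_hits(ev, lexicon)
  hits$index_time <- idx_num[match(hits$user_id, index_times$user_id)]
  hits$offset_days <- (as.numeric(hits$timestamp) - hits$index_time) / DAY

  grid <- tidyr_expand_grid(lexicon_symptoms(lexicon), windows$label)
  count_distinct <- function(h) {
    h <- dplyr::distinct(h, .data$user_id, .data$symptom)
    dplyr::count(h, .data$symptom, name = "n")
  }
  base_hits <- hits[hits$offset_days < -LEADUP_DAYS &
                      hits$timestamp >= span_start, , drop = FALSE]
  b_counts <- count_distinct(base_hits)
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    wh <- hits[hits$offset_days >= w$start_day &
                 hits$offset_days < w$end_day, , drop = FALSE]
    a_counts <- count_distinct(wh)
    g <- tibble(symptom = lexicon_symptoms(lexicon), window = w$label)
    g <- dplyr::left_join(g, a_counts, by = "symptom")
    g$A <- dplyr::coalesce(g$n, 0L)
    g$n <- NULL
    g <- dplyr::left_join(g, b_counts, by = "symptom")
    g$B <- dplyr::coalesce(g$n, 0L)
    g$n <- NULL
    out[[i]] <- g
  }
  tables <- dplyr::bind_rows(out)
  tables$C <- n_eval - tables$A
  tables$D <- n_eval - tables$B
  attr(tables, "n_evaluated") <- n_eval
  attr(tables, "n_dropped") <- n_dropped
  tables
}

# small local stand-in to avoid importing tidyr for one call
tidyr_expand_grid <- function(a, b) {
  tibble(symptom = rep(a, each = length(b)), window = rep(b, length(a)))
}

#' Person-level 2x2 table for one (symptom, window) pair
#'
#' Cell counts over the evaluable target users (those whose baseline period
#' `[span_start, index - 30d)` is at least one day long; the rest are dropped
#' and counted):
#' * `A` — users with >= 1 query matching the symptom inside the window
#'   (offsets taken relative to each user's own index time); `C` — the rest;
#' * `B` — users with >= 1 matching query in their baseline period; `D` — the
#'   rest.
#'
#' By construction `A + C == B + D ==` the number of evaluated users.
#'
#' @param target_events event tibble of the target cohort.
#' @param index_times tibble with `user_id`, `index_time` for target users.
#' @param symptom canonical symptom name.
#' @param lexicon a [symptom_lexicon()].
#' @param window a single row of [window_specs()] (or its label).
#' @param span_start start of the observation span (baseline lower bound).
#' @return one-row tibble with `symptom`, `window`, `A`, `B`, `C`, `D` and
#'   attributes `n_evaluated`, `n_dropped`.
#' @export
build_window_table <- function(target_events, index_times, symptom, lexicon,
                               window, span_start) {
  windows <- window_specs()
  if (is.character(window)) {
    stopifnot(window %in% windows$label)
    windows <- windows[windows$label == window, ]
  } else {
    windows <- as_tibble(window)
  }
  tables <- window_tables_all(target_events, index_times, lexicon, windows,
                              span_start)
  out <- tables[tables$symptom == symptom, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("symptom not in lexicon: ", symptom, call. = FALSE)
  }
  attr(out, "n_evaluated") <- attr(tables, "n_evaluated")
  attr(out, "n_dropped") <- attr(tables, "n_dropped")
  out
}

#' Pearson chi-square for a person-level 2x2 table
#'
#' The closed form `n (AD - BC)^2 / ((A+B)(C+D)(A+C)(B+D))` on the table with
#' rows `(A, C)` (window period) and `(B, D)` (baseline period), one degree of
#' freedom, upper-tail p-value, and no continuity correction by default. A
#' zero margin makes the table degenerate: statistic 0, p-value 1, and the
#' `degenerate` flag set.
#'
#' @param A,B,C,D non-negative cell counts (vectorized).
#' @param correct apply the Yates continuity correction.
#' @return tibble with columns `statistic`, `p_value`, `degenerate`.
#' @export
pearson_chi_square <- function(A, B, C, D, correct = FALSE) {
  if (any(c(A, B, C, D) < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  n <- A + B + C + D
  denom <- (A + B) * (C + D) * (A + C) * (B + D)
  degenerate <- denom == 0
  num <- abs(A * D - B * C)
  if (correct) {
    num <- pmax(num - n / 2, 0)
  }
  statistic <- ifelse(degenerate, 0, n * num^2 / ifelse(degenerate, 1, denom))
  p_value <- ifelse(degenerate, 1,
                    stats::pchisq(statistic, df = 1, lower.tail = FALSE))
  tibble(statistic = statistic, p_value = p_value, degenerate = degenerate)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control over all (symptom, window) tests:
#' `alpha / (n_symptoms * n_windows)`. The symptom count is always the number
#' of symptoms actually tested (the supplied lexicon's size), never a
#' hard-coded constant.
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_symptoms number of symptoms tested.
#' @param n_windows number of lead-up windows (3 by default elsewhere).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_symptoms, n_windows) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha <= 1)
  if (n_symptoms <= 0 || n_windows <= 0) {
    stop("n_symptoms and n_windows must be positive", call. = FALSE)
  }
  alpha / (n_symptoms * n_windows)
}

#' Time-lagged within-person temporal screen
#'
#' For every (symptom, window) pair, compares the fraction of target users
#' querying the symptom inside the lead-up window against the fraction
#' querying it in their baseline period (all activity strictly before
#' index - 30 days), via the Pearson chi-square on the person-level 2x2
#' table. A pair is flagged significant only when the window probability
#' exceeds the baseline probability AND the p-value clears the
#' Bonferroni-corrected threshold over all (symptom, window) tests.
#'
#' Note the deliberate asymmetry inherited from the underlying method: the
#' window (7 or 16 days) and the baseline (typically months) are compared as
#' raw person-level probabilities without duration normalization, so the
#' screen only has power for symptoms whose baseline person-prevalence is low
#' relative to the window prevalence (see the package vignette).
#'
#' @inheritParams build_window_table
#' @param windows window table, default [window_specs()].
#' @param alpha family-wise level before correction.
#' @param correct Yates continuity correction flag.
#' @return tibble with one row per (symptom, window): cells `A`, `B`, `C`,
#'   `D`, `p_window`, `p_baseline`, `chi_square`, `p_value`, `significant`.
#'   Attributes: `n_symptoms_tested`, `n_windows`, `threshold`, `alpha`,
#'   `n_evaluated`, `n_dropped`.
#' @export
temporal_screen <- function(target_events, index_times, lexicon, span_start,
                            windows = window_specs(), alpha = 0.05,
                            correct = FALSE) {
  tables <- window_tables_all(target_events, index_times, lexicon, windows,
                              span_start)
  chi <- pearson_chi_square(tables$A, tables$B, tables$C, tables$D,
                            correct = correct)
  n_symptoms <- length(lexicon_symptoms(lexicon))
  threshold <- bonferroni_threshold(alpha, n_symptoms, nrow(as_tibble(windows)))
  out <- tables
  out$p_window <- out$A / (out$A + out$C)
  out$p_baseline <- out$B / (out$B + out$D)
  out$chi_square <- chi$statistic
  out$p_value <- chi$p_value
  out$significant <- !chi$degenerate &
    out$p_window > out$p_baseline & out$p_value < threshold
  attr(out, "n_symptoms_tested") <- n_symptoms
  attr(out, "n_windows") <- nrow(as_tibble(windows))
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "n_evaluated") <- attr(tables, "n_evaluated")
  attr(out, "n_dropped") <- attr(tables, "n_dropped")
  attr(out, "duration_normalized") <- FALSE
  out
}

PERSISTENCE_LEVELS <- c("persistent", "near_persistent", "immediate",
                        "distal", "middle_only", "none")

#' Persistence taxonomy of significant symptoms
#'
#' Classifies each symptom by the set of lead-up windows in which its
#' querying increase is significant:
#' * `persistent` — all three windows;
#' * `near_persistent` — exactly two windows;
#' * `immediate` — the proximal window only;
#' * `distal` — the distal window only;
#' * `middle_only` — the middle window only;
#' * `none` — no significant window.
#'
#' Every symptom receives exactly one category.
#'
#' @param results output of [temporal_screen()] (needs columns `symptom`,
#'   `window`, `significant`; exactly three windows per symptom).
#' @return tibble with columns `symptom`, `category` (factor with the levels
#'   above) and `windows` (comma-joined significant window labels).
#' @export
classify_persistence <- function(results) {
  results <- as_tibble(results)
  stopifnot(all(c("symptom", "window", "significant") %in% names(results)))
  counts <- table(results$symptom)
  if (any(counts != 3)) {
    stop("every symptom needs exactly three window results; offending: ",
         paste(names(counts)[counts != 3], collapse = ", "), call. = FALSE)
  }
  order_windows <- c("distal", "middle", "proximal")
  sig <- results[results$significant, c("symptom", "window")]
  per_symptom <- split(sig$window, factor(sig$symptom,
                                          levels = unique(results$symptom)))
  category <- vapply(per_symptom, function(w) {
    n <- length(w)
    if (n == 3) "persistent"
    else if (n == 2) "near_persistent"
    else if (n == 1) {
      switch(w, proximal = "immediate", distal = "distal",
             middle = "middle_only")
    } else "none"
  }, character(1))
  windows_str <- vapply(per_symptom, function(w) {
    paste(order_windows[order_windows %in% w], collapse = ",")
  }, character(1))
  tibble(
    symptom = names(per_symptom),
    category = factor(unname(category), levels = PERSISTENCE_LEVELS),
    windows = unname(windows_str)
  )
}

#' Chi-square comparison of symptom querying between two subgroups
#'
#' Person-level 2x2 test (subgroup membership x queried-the-symptom
#' indicator) of whether two target subgroups (e.g. all treatment
#' information seekers versus meeting-locator seekers) query a symptom at
#' different rates.
#'
#' @param events_a,events_b event tibbles for the two subgroups (non-empty).
#' @param symptom canonical symptom name.
#' @param lexicon a [symptom_lexicon()].
#' @param correct Yates continuity correction flag.
#' @return one-row tibble with `statistic`, `p_value`, `degenerate`.
#' @export
compare_subgroups <- function(events_a, events_b, symptom, lexicon,
                              correct = FALSE) {
  n_a <- dplyr::n_distinct(events_a$user_id)
  n_b <- dplyr::n_distinct(events_b$user_id)
  if (n_a == 0 || n_b == 0) {
    stop("both subgroups must be non-empty", call. = FALSE)
  }
  queried <- function(events, n) {
    h <- symptom_hits(events, lexicon)
    sum(!duplicated(h$user_id[h$symptom == symptom]))
  }
  qa <- queried(events_a, n_a)
  qb <- queried(events_b, n_b)
  pearson_chi_square(A = qa, B = qb, C = n_a - qa, D = n_b - qb,
                     correct = correct)
}
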
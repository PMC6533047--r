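# Shared fixture builders: everything is generated in code at test time.

utc <- function(x) as.POSIXct(x, tz = "UTC")

tiny_lexicon <- function() {
  symptom_lexicon(c(
    diaphoresis = "sweating",
    pyrosis = "heartburn",
    rash = "skin rash",
    "back pain" = "back ache"
  ))
}

# A hand-built log: three users over a 2017 span with an index window in
# September; u1 is a clean target, u2 a prior seeker, u3 never seeks.
toy_cohort_log <- function() {
  events <- tibble::tibble(
    user_id = c("u1", "u1", "u2", "u2", "u3"),
    timestamp = utc(c(
      "2017-05-01 10:00:00",  # u1 background
      "2017-09-10 09:30:00",  # u1 first seed query (in index window)
      "2017-03-02 08:00:00",  # u2 seed query before the window
      "2017-09-05 11:00:00",  # u2 seed query again, inside the window
      "2017-04-20 16:00:00"   # u3 background
    )),
    query_text = c(
      "weather tomorrow",
      "aa meeting near me",
      "alcoholics anonymous",
      "aa meeting near me",
      "chocolate cake recipe"
    ),
    clicked_url = c(NA, "https://aa.example/meet", "https://aa.example/", NA, NA)
  )
  search_log(events, "2017-01-01", "2017-10-01")
}

toy_seeds <- function() {
  tibble::tibble(
    query_text = c("aa meeting near me", "alcoholics anonymous",
                   "narcotics anonymous"),
    label = c("AA", "AA", "NA"),
    n_users = c(100L, 100L, 100L),
    is_meeting = c(TRUE, FALSE, FALSE)
  )
}

# Small seeded simulation used by several property tests.
small_sim <- function(seed = 1, n_target = 40, n_comparison = 150,
                      n_symptoms = 8, ...) {
  cfg <- null_config(n_symptoms, seed = seed, n_target_users = n_target,
                     n_comparison_users = n_comparison, ...)
  simulate_logs(cfg)
}

target_index_times <- function(sim) {
  u <- sim$truth$users
  u[u$role == "target", c("user_id", "index_time")]
}

# Events placed at exact offsets (in days) before a common index time, on a
# span long enough that every user is evaluable.
offset_log <- function(user_offsets, query_text = "heartburn",
                       span_start = "2017-01-01", index = "2017-03-15 12:00:00",
                       span_end = "2017-04-01") {
  index <- utc(index)
  rows <- lapply(names(user_offsets), function(u) {
    off <- user_offsets[[u]]
    tibble::tibble(
      user_id = u,
      timestamp = index - off * 86400,
      query_text = query_text,
      clicked_url = NA_character_
    )
  })
  events <- dplyr::bind_rows(rows)
  # anchor every user with one background event so all users appear
  anchor <- tibble::tibble(
    user_id = names(user_offsets), timestamp = utc(span_start) + 3600,
    query_text = "zzz background zzz", clicked_url = NA_character_
  )
  list(
    log = search_log(dplyr::bind_rows(events, anchor), span_start, span_end),
    index_times = tibble::tibble(
      user_id = names(user_offsets),
      index_time = rep(index, length(user_offsets))
    )
  )
}
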
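make_click_log <- function(n_aa = 60, n_low = 10, n_nonseed = 20) {
  mk <- function(prefix, n, query, url) {
    tibble::tibble(
      user_id = sprintf("%s%03d", prefix, seq_len(n)),
      timestamp = utc("2017-09-05 10:00:00") + seq_len(n),
      query_text = query,
      clicked_url = url
    )
  }
  events <- dplyr::bind_rows(
    mk("a", n_aa, "AA Meeting near me!", "https://aa.example/meet"),
    mk("b", n_low, "alcoholics anonymous steps", "https://aa.example/"),
    mk("c", n_nonseed, "aa meeting near me", "https://blog.example/aa-story")
  )
  search_log(events, "2017-01-01", "2017-10-01")
}

aa_na_urls <- tibble::tibble(
  url = c("https://aa.example/", "https://aa.example/meet",
          "https://na.example/"),
  label = c("AA", "AA", "NA")
)

test_that("seed queries are retained at the user threshold and labeled", {
  log <- make_click_log()
  seeds <- discover_seed_queries(log, aa_na_urls, min_users = 50)
  # 60 distinct users with a seed click -> retained, normalized, AA, meeting
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$query_text, "aa meeting near me")
  expect_equal(seeds$label, "AA")
  expect_equal(seeds$n_users, 60L)
  expect_true(seeds$is_meeting)
  # the 10-user query appears once the threshold drops
  seeds10 <- discover_seed_queries(log, aa_na_urls, min_users = 10)
  expect_setequal(seeds10$query_text,
                  c("aa meeting near me", "alcoholics anonymous steps"))
  expect_false(seeds10$is_meeting[seeds10$query_text == "alcoholics anonymous steps"])
  # clicks to non-seed URLs never qualify
  expect_false(any(grepl("blog", seeds10$query_text)))
  expect_error(discover_seed_queries(log, aa_na_urls[0, ]), "non-empty")
})

test_that("mixed AA/NA clicks are labeled by majority, ties BOTH", {
  ev <- tibble::tibble(
    user_id = sprintf("u%02d", 1:6),
    timestamp = utc("2017-09-01 00:00:00") + 1:6,
    query_text = "twelve step program",
    clicked_url = c("https://aa.example/", "https://aa.example/",
                    "https://na.example/", "https://na.example/",
                    "https://aa.example/", "https://na.example/")
  )
  log <- search_log(ev, "2017-01-01", "2017-10-01")
  seeds <- discover_seed_queries(log, aa_na_urls, min_users = 1)
  expect_equal(seeds$label, "BOTH")
  ev$clicked_url[6] <- "https://aa.example/"
  seeds <- discover_seed_queries(search_log(ev, "2017-01-01", "2017-10-01"),
                                 aa_na_urls, min_users = 1)
  expect_equal(seeds$label, "AA")
})

test_that("identify_cohort applies the first-seed-in-final-month rule", {
  log <- toy_cohort_log()
  cohort <- identify_cohort(log, toy_seeds())
  roles <- stats::setNames(cohort$role, cohort$user_id)
  expect_equal(unname(roles[c("u1", "u2", "u3")]),
               c("target", "excluded", "comparison"))
  expect_equal(cohort$index_time[cohort$user_id == "u1"],
               utc("2017-09-10 09:30:00"))
  expect_true(is.na(cohort$index_time[cohort$user_id == "u3"]))
  expect_error(identify_cohort(log, toy_seeds(),
                               index_window = c("2017-09-01", "2017-12-01")),
               "within the log span")
})

test_that("subgroups and the meeting flag follow the index-window queries", {
  events <- tibble::tibble(
    user_id = c("aa_only", "both1", "both1", "meetless"),
    timestamp = utc(c("2017-09-03 10:00:00", "2017-09-04 10:00:00",
                      "2017-09-20 10:00:00", "2017-09-05 10:00:00")),
    query_text = c("aa meeting near me", "narcotics anonymous",
                   "aa meeting near me", "alcoholics anonymous"),
    clicked_url = NA_character_
  )
  log <- search_log(events, "2017-01-01", "2017-10-01")
  cohort <- assign_subgroups(identify_cohort(log, toy_seeds()), log, toy_seeds())
  row <- function(u) cohort[cohort$user_id == u, ]
  expect_equal(row("aa_only")$group, "AA")
  expect_true(row("aa_only")$meeting_subsample)
  expect_equal(row("both1")$group, "BOTH")
  expect_false(row("both1")$meeting_subsample)  # first query was NA, non-meeting
  expect_equal(row("meetless")$group, "AA")
  expect_false(row("meetless")$meeting_subsample)
})

test_that("cohort roles partition the users of seeded simulated logs", {
  for (seed in c(4, 8)) {
    sim <- small_sim(seed = seed, n_target = 35, n_comparison = 90)
    seeds <- discover_seed_queries(sim$log,
                                   read_seed_urls(default_seed_urls_path()),
                                   min_users = 1)
    cohort <- assign_subgroups(identify_cohort(sim$log, seeds), sim$log, seeds)
    expect_equal(sort(cohort$user_id), sort(unique(sim$log$events$user_id)))
    expect_equal(sum(cohort$role %in% c("target", "comparison", "excluded")),
                 nrow(cohort))
    is_t <- cohort$role == "target"
    # AA + NA + BOTH == target
    expect_equal(sum(cohort$group[is_t] == "AA") +
                   sum(cohort$group[is_t] == "NA") +
                   sum(cohort$group[is_t] == "BOTH"),
                 sum(is_t))
    # every target's index time is their earliest seed event, inside the window
    expect_true(all(cohort$index_time[is_t] >= utc("2017-07-01")))
    # against ground truth (min_users = 1 discovers every seed string)
    truth <- sim$truth$users
    expect_equal(sort(cohort$user_id[is_t]),
                 sort(truth$user_id[truth$role == "target"]))
    expect_equal(
      cohort$group[is_t][order(cohort$user_id[is_t])],
      truth$group[truth$role == "target"][order(truth$user_id[truth$role == "target"])]
    )
  }
})

test_that("keyword_fraction computes the token proportion of seed events", {
  n <- 50
  events <- tibble::tibble(
    user_id = sprintf("u%03d", seq_len(n)),
    timestamp = utc("2017-09-02 00:00:00") + seq_len(n),
    query_text = c("alanon aa meeting near me",
                   rep("aa meeting near me", n - 1)),
    clicked_url = NA_character_
  )
  log <- search_log(events, "2017-01-01", "2017-10-01")
  seeds <- tibble::tibble(
    query_text = c("alanon aa meeting near me", "aa meeting near me"),
    label = "AA", n_users = c(1L, 49L), is_meeting = TRUE
  )
  expect_equal(keyword_fraction(log, events$user_id, "alanon", seeds), 0.02)
  expect_equal(keyword_fraction(log, events$user_id, "sponsor", seeds), 0)
  expect_error(keyword_fraction(log, "nobody", "alanon", seeds),
               "no seed-query events")

  # Monte-Carlo: planted 5% keyword fraction recovered within 3 binomial SE
  set.seed(7)
  n <- 800
  planted <- stats::rbinom(n, 1, 0.05) == 1
  events <- tibble::tibble(
    user_id = sprintf("u%04d", seq_len(n)),
    timestamp = utc("2017-09-02 00:00:00") + seq_len(n),
    query_text = ifelse(planted, "alanon aa meeting near me",
                        "aa meeting near me"),
    clicked_url = NA_character_
  )
  log <- search_log(events, "2017-01-01", "2017-10-01")
  est <- keyword_fraction(log, events$user_id, "alanon", seeds)
  expect_lt(abs(est - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("cohort tables round-trip through their tab-separated form", {
  sim <- small_sim(seed = 6, n_target = 20, n_comparison = 30)
  seeds <- discover_seed_queries(sim$log,
                                 read_seed_urls(default_seed_urls_path()),
                                 min_users = 1)
  cohort <- assign_subgroups(identify_cohort(sim$log, seeds), sim$log, seeds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  expect_equal(read_cohort(path), cohort)
})
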
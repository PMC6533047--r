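test_that("window specs partition the 30-day lead-up", {
  w <- window_specs()
  expect_equal(sort(w$label), c("distal", "middle", "proximal"))
  expect_equal(sum(w$end_day - w$start_day), 30)
  expect_equal(min(w$start_day), -30)
  expect_equal(max(w$end_day), 0)
})

test_that("symptom_user_probability counts users once per period", {
  lex <- tiny_lexicon()
  ol <- offset_log(list(u1 = c(2, 3), u2 = 40, u3 = numeric(0)))
  h <- ol$log$events
  expect_equal(symptom_user_probability(h, "pyrosis", lex), 2 / 3)
  expect_equal(symptom_user_probability(h, "rash", lex), 0)
  expect_equal(
    symptom_user_probability(h, "pyrosis", lex,
                             period = c("2017-03-10", "2017-03-16")),
    1 / 3
  )
  expect_error(symptom_user_probability(h[0, ], "pyrosis", lex), "no users")
})

test_that("person-level probability matches the Bernoulli closed form", {
  # 30 observed days at per-day probability 0.01: P(>=1 query) = 1 - 0.99^30
  cfg <- null_config(3, seed = 17, n_target_users = 0,
                     n_comparison_users = 400,
                     span_start = "2017-01-01", span_end = "2017-03-01")
  sim <- simulate_logs(cfg)
  lex <- sim_lexicon(cfg)
  p_expected <- 1 - 0.99^30
  period <- c("2017-01-01", "2017-01-31")
  se <- sqrt(p_expected * (1 - p_expected) / 400)
  for (s in cfg$symptoms) {
    phat <- symptom_user_probability(sim$log$events, s, lex, period = period)
    expect_lt(abs(phat - p_expected), 3 * se)
  }
})

test_that("window tables match hand enumeration on the 3-user toy log", {
  lex <- tiny_lexicon()
  # u1 queries the symptom only in the proximal window, u2 only in baseline,
  # u3 never
  ol <- offset_log(list(u1 = 2, u2 = 40, u3 = numeric(0)))
  tab_prox <- build_window_table(ol$log$events, ol$index_times, "pyrosis",
                                 lex, "proximal", ol$log$span_start)
  expect_equal(tab_prox[, c("A", "B", "C", "D")],
               tibble::tibble(A = 1L, B = 1L, C = 2L, D = 2L),
               ignore_attr = TRUE)
  tab_dist <- build_window_table(ol$log$events, ol$index_times, "pyrosis",
                                 lex, "distal", ol$log$span_start)
  expect_equal(tab_dist[, c("A", "B", "C", "D")],
               tibble::tibble(A = 0L, B = 1L, C = 3L, D = 2L),
               ignore_attr = TRUE)
})

test_that("saturated tables have A=B=n and C=D=0", {
  lex <- tiny_lexicon()
  ol <- offset_log(list(u1 = c(2, 10, 20, 40), u2 = c(3, 9, 16, 50)))
  scr <- temporal_screen(ol$log$events, ol$index_times, lex,
                         ol$log$span_start)
  py <- scr[scr$symptom == "pyrosis", ]
  expect_true(all(py$A == 2 & py$B == 2 & py$C == 0 & py$D == 0))
  expect_true(all(py$chi_square == 0))
})

test_that("window/baseline conservation holds on simulated cohorts", {
  sim <- small_sim(seed = 19, n_target = 25, n_comparison = 40)
  lex <- read_lexicon(default_lexicon_path())
  scr <- temporal_screen(sim$log$events, target_index_times(sim), lex,
                         sim$log$span_start)
  n_eval <- attr(scr, "n_evaluated")
  expect_gt(n_eval, 0)
  expect_true(all(scr$A + scr$C == n_eval))
  expect_true(all(scr$B + scr$D == n_eval))
  expect_equal(nrow(scr), lex$size * 3)
})

test_that("the chi-square closed form matches its reference implementation", {
  res <- pearson_chi_square(10, 5, 90, 95)
  expect_equal(res$statistic, 200 * (10 * 95 - 90 * 5)^2 /
                 (100 * 100 * 15 * 185))
  expect_equal(res$statistic, 1.801802, tolerance = 1e-6)
  # p-value against the reference chi-square distribution
  expect_equal(res$p_value,
               stats::chisq.test(matrix(c(10, 5, 90, 95), 2),
                                 correct = FALSE)$p.value)
  # identical rows: no association
  expect_equal(pearson_chi_square(5, 5, 5, 5)$statistic, 0)
  expect_equal(pearson_chi_square(5, 5, 5, 5)$p_value, 1)
  # degenerate margins
  deg <- pearson_chi_square(0, 0, 0, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  deg2 <- pearson_chi_square(0, 3, 0, 7)
  expect_true(deg2$degenerate)
  expect_error(pearson_chi_square(-1, 2, 3, 4), "non-negative")
  # Yates correction agrees with the reference implementation
  y <- pearson_chi_square(12, 4, 88, 96, correct = TRUE)
  ref <- stats::chisq.test(matrix(c(12, 4, 88, 96), 2), correct = TRUE)
  expect_equal(y$statistic, unname(ref$statistic))
  expect_equal(y$p_value, ref$p.value)
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.06, 3, 2), 0.01)
  expect_error(bonferroni_threshold(0.05, 0, 3), "positive")
})

test_that("the temporal screen flags a hand-planted proximal elevation", {
  lex <- tiny_lexicon()
  # 120 users; 60 query the symptom 3 days before index, none at baseline;
  # all users also have a baseline back-ache query so the log spans time
  n <- 120
  users <- sprintf("u%03d", seq_len(n))
  offsets <- stats::setNames(
    c(lapply(seq_len(60), function(i) 3), lapply(61:120, function(i) numeric(0))),
    users
  )
  ol <- offset_log(offsets)
  scr <- temporal_screen(ol$log$events, ol$index_times, lex,
                         ol$log$span_start)
  prox <- scr[scr$symptom == "pyrosis" & scr$window == "proximal", ]
  expect_true(prox$significant)
  expect_gt(prox$p_window, prox$p_baseline)
  cls <- classify_persistence(scr)
  expect_equal(as.character(cls$category[cls$symptom == "pyrosis"]),
               "immediate")
  # everything else stays quiet
  expect_equal(sum(scr$significant), 1L)
})

test_that("a single-user cohort yields no significant result and no crash", {
  lex <- tiny_lexicon()
  ol <- offset_log(list(u1 = c(2, 40)))
  scr <- temporal_screen(ol$log$events, ol$index_times, lex,
                         ol$log$span_start)
  expect_false(any(scr$significant))
  expect_equal(attr(scr, "n_evaluated"), 1L)
})

test_that("users with short pre-index observation are dropped and counted", {
  lex <- tiny_lexicon()
  ol <- offset_log(list(u1 = 2, u2 = 40))
  # u3 indexes 10 days into the span: baseline would be empty
  late <- tibble::tibble(user_id = "u3", index_time = utc("2017-01-11"))
  events <- dplyr::bind_rows(
    ol$log$events,
    tibble::tibble(user_id = "u3", timestamp = utc("2017-01-05"),
                   query_text = "heartburn", clicked_url = NA_character_)
  )
  scr <- temporal_screen(events, dplyr::bind_rows(ol$index_times, late), lex,
                         ol$log$span_start)
  expect_equal(attr(scr, "n_evaluated"), 2L)
  expect_equal(attr(scr, "n_dropped"), 1L)
  expect_true(all(scr$A + scr$C == 2))
})

test_that("persistence classification covers all categories and partitions", {
  mk <- function(symptom, sig) {
    tibble::tibble(symptom = symptom, window = c("distal", "middle", "proximal"),
                   significant = sig)
  }
  res <- dplyr::bind_rows(
    mk("s_all", c(TRUE, TRUE, TRUE)),
    mk("s_two", c(FALSE, TRUE, TRUE)),
    mk("s_prox", c(FALSE, FALSE, TRUE)),
    mk("s_dist", c(TRUE, FALSE, FALSE)),
    mk("s_mid", c(FALSE, TRUE, FALSE)),
    mk("s_none", c(FALSE, FALSE, FALSE))
  )
  cls <- classify_persistence(res)
  got <- stats::setNames(as.character(cls$category), cls$symptom)
  expect_equal(unname(got[c("s_all", "s_two", "s_prox", "s_dist", "s_mid",
                            "s_none")]),
               c("persistent", "near_persistent", "immediate", "distal",
                 "middle_only", "none"))
  expect_equal(nrow(cls), 6L)
  expect_false(anyDuplicated(cls$symptom) > 0)
  expect_equal(cls$windows[cls$symptom == "s_two"], "middle,proximal")
  expect_error(classify_persistence(res[-1, ]), "exactly three")

  # property: random significance patterns always give exactly one category
  set.seed(12)
  for (rep in 1:20) {
    syms <- paste0("s", 1:8)
    res <- dplyr::bind_rows(lapply(syms, function(s) {
      mk(s, stats::runif(3) < 0.4)
    }))
    cls <- classify_persistence(res)
    expect_setequal(cls$symptom, syms)
    expect_false(anyNA(cls$category))
  }
})

test_that("probability_ratio_screen ranks by descending ratio", {
  lex <- tiny_lexicon()
  mk_events <- function(prefix, n, n_sym, sym_text) {
    tibble::tibble(
      user_id = rep(sprintf("%s%03d", prefix, seq_len(n)), 2),
      timestamp = utc("2017-02-01") + seq_len(2 * n),
      query_text = c(rep(sym_text, n_sym), rep("nothing here", n - n_sym),
                     rep("filler", n)),
      clicked_url = NA_character_
    )
  }
  target <- mk_events("t", 100, 5, "heartburn")
  comparison <- mk_events("c", 1000, 10, "heartburn")
  rr <- probability_ratio_screen(target, comparison, lex)
  py <- rr[rr$symptom == "pyrosis", ]
  expect_equal(py$p_target, 0.05)
  expect_equal(py$p_comparison, 0.01)
  expect_equal(py$ratio, 5)
  expect_equal(py$rank, 1L)
  # symptoms absent from the comparison side have undefined ratio, no rank
  expect_true(all(is.na(rr$rank[rr$p_comparison == 0])))
  # identical populations give ratio 1 everywhere it is defined
  rr_same <- probability_ratio_screen(comparison, comparison, lex)
  expect_true(all(rr_same$ratio[!is.na(rr_same$ratio)] == 1))
})

test_that("a whole-history x10 elevation is ranked first", {
  reps <- 6
  top <- character(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(
      n_target_users = 2000, n_comparison_users = 20000,
      symptoms = lexicon_symptoms(read_lexicon(default_lexicon_path()))[1:10],
      planted_effects = data.frame(symptom = "urticaria", window = "all",
                                   multiplier = 10),
      rng_seed = 100 + i
    )
    sim <- simulate_logs(cfg)
    lex <- sim_lexicon(cfg)
    u <- sim$truth$users
    ev <- sim$log$events
    t_ev <- ev[ev$user_id %in% u$user_id[u$role == "target"], ]
    c_ev <- ev[ev$user_id %in% u$user_id[u$role == "comparison"], ]
    rr <- probability_ratio_screen(t_ev, c_ev, lex)
    top[i] <- rr$symptom[rr$rank == 1 & !is.na(rr$rank)]
    if (i == 1) {
      # null symptoms stay near ratio 1
      null_ratios <- rr$ratio[rr$symptom != "urticaria" & !is.na(rr$ratio)]
      expect_lt(abs(stats::median(null_ratios) - 1), 0.25)
    }
  }
  expect_true(all(top == "urticaria"))
})

test_that("compare_subgroups matches the closed form and controls size", {
  lex <- tiny_lexicon()
  mk <- function(prefix, n, k) {
    tibble::tibble(
      user_id = sprintf("%s%04d", prefix, seq_len(n)),
      timestamp = utc("2017-02-01") + seq_len(n),
      query_text = c(rep("heartburn", k), rep("nothing", n - k)),
      clicked_url = NA_character_
    )
  }
  # identical frequencies: no signal
  same <- compare_subgroups(mk("a", 100, 30), mk("b", 100, 30), "pyrosis", lex)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # (30/100 vs 10/100) against the closed form
  got <- compare_subgroups(mk("a", 100, 30), mk("b", 100, 10), "pyrosis", lex)
  n <- 200
  expect_equal(got$statistic, n * (30 * 90 - 10 * 70)^2 / (40 * 160 * 100 * 100))
  expect_error(compare_subgroups(mk("a", 100, 30)[0, ], mk("b", 5, 1),
                                 "pyrosis", lex), "non-empty")

  # a random subsample of a population is not significantly different
  set.seed(31)
  n_pop <- 400
  rejections <- 0L
  pop <- mk("p", n_pop, 60)
  for (rep in 1:100) {
    sub_users <- sample(unique(pop$user_id), 150)
    sub <- pop[pop$user_id %in% sub_users, ]
    res <- compare_subgroups(pop, sub, "pyrosis", lex)
    rejections <- rejections + (res$p_value < 0.05)
  }
  expect_lte(rejections, 10L)
})
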
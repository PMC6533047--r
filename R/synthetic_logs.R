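DAY <- 86400

month_floor <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$mday <- 1L
  lt$hour <- lt$min <- lt$sec <- 0L
  as.POSIXct(lt)
}

#' Default 12-step seed-query vocabulary for the generator
#'
#' Query strings target users may issue as their first treatment-seeking
#' query, each paired with the 12-step resource page it clicks through to and
#' labeled by program (AA or NA) and whether it is a meeting-locator query.
#' The URLs match the packaged seed-URL fixture ([default_seed_urls_path()]).
#'
#' @return tibble with columns `query_text`, `program`, `is_meeting`, `url`.
#' @export
default_seed_vocabulary <- function() {
  tibble(
    query_text = c(
      "alcoholics anonymous", "aa twelve steps", "aa meeting near me",
      "alcoholic anonymous meeting directory", "narcotics anonymous",
      "na information", "na meeting locator"
    ),
    program = c("AA", "AA", "AA", "AA", "NA", "NA", "NA"),
    is_meeting = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    url = c(
      "https://www.aa.example.org/",
      "https://www.aa.example.org/twelve-steps",
      "https://www.aa.example.org/find-a-meeting",
      "https://intergroup.aa.example.org/meetings",
      "https://www.na.example.org/",
      "https://www.na.example.org/information",
      "https://www.na.example.org/meetingsearch"
    )
  )
}

#' Path to the packaged seed-URL fixture
#' @return file path to a two-column (url, label) tab-separated file.
#' @export
default_seed_urls_path <- function() {
  system.file("extdata", "seed_urls.tsv", package = "symptomlag",
              mustWork = TRUE)
}

# Fabricated non-words: background queries must never match a lexicon synonym.
BACKGROUND_WORDS <- c(
  "zorvel", "quentish", "blarpo", "mizzleten", "frubbix", "woxit", "dramber",
  "plonk", "snibbet", "varkle", "jupped", "crondle", "melvix", "torbane",
  "glimber", "hustrop", "naffick", "yorvel", "skendal", "pruvott", "ombrix",
  "tavock", "wendrip", "luzzern", "kippage", "sorbell", "drazzle", "finnock",
  "gorvance", "hylter"
)

PLANT_WINDOWS <- c("distal", "middle", "proximal", "all")

#' Configuration for the synthetic search-log generator
#'
#' Defines the simulated data regime: per-user background querying, per-day
#' Bernoulli symptom querying, one cohort of treatment seekers whose first
#' 12-step seed query falls in the final calendar month of the span, and
#' optional planted window-specific symptom-rate multipliers against which the
#' temporal screen can be calibrated.
#'
#' @param n_target_users number of treatment-seeking (target) users.
#' @param n_comparison_users number of comparison users (no seed queries).
#' @param span_start,span_end half-open observation span; defaults to the
#'   nine months 2016-11-01 to 2017-08-01 (UTC).
#' @param background_query_rate expected background (non-symptom, non-seed)
#'   queries per user-day; Poisson intensity.
#' @param symptom_base_prob probability that a user queries a given symptom on
#'   a given day (per-symptom per-user-day Bernoulli, so a user queries a
#'   symptom at most once per day, matching the person-level counting the
#'   screens use).
#' @param symptoms character vector of canonical symptom names the generator
#'   emits; defaults to the packaged fixture lexicon's symptoms.
#' @param planted_effects `NULL` or a data frame with columns `symptom`,
#'   `window` (one of `"distal"`, `"middle"`, `"proximal"`, or `"all"` for a
#'   whole-history elevation) and `multiplier` (>= 1). Multipliers apply to
#'   target users' emission probability on days falling in the stated window
#'   relative to their own index time.
#' @param seed_vocabulary seed-query vocabulary, see
#'   [default_seed_vocabulary()].
#' @param group_weights sampling weights for target subgroup membership,
#'   named `AA`, `NA`, `BOTH`; defaults mirror the published cohort mix
#'   (10522 : 1022 : 240).
#' @param meeting_prob probability that a target user's first seed query is a
#'   meeting-locator query; default mirrors the published 3820/11784.
#' @param background_click_prob probability a background query records a
#'   click (to a non-seed URL).
#' @param rng_seed integer seed; the generator is a pure function of the
#'   configuration including this seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_target_users,
                       n_comparison_users,
                       span_start = "2016-11-01",
                       span_end = "2017-08-01",
                       background_query_rate = 0.1,
                       symptom_base_prob = 0.01,
                       symptoms = NULL,
                       planted_effects = NULL,
                       seed_vocabulary = default_seed_vocabulary(),
                       group_weights = c(AA = 10522, `NA` = 1022, BOTH = 240),
                       meeting_prob = 3820 / 11784,
                       background_click_prob = 0.3,
                       rng_seed = 1L) {
  span_start <- as_instant_scalar(span_start, "span_start")
  span_end <- as_instant_scalar(span_end, "span_end")
  if (as.numeric(span_end - span_start, units = "days") < 31) {
    stop("span must be at least 31 days (the lead-up windows would not fit)",
         call. = FALSE)
  }
  if (is.null(symptoms)) {
    symptoms <- lexicon_symptoms(read_lexicon(default_lexicon_path()))
  }
  symptoms <- as.character(symptoms)
  if (anyDuplicated(symptoms)) {
    stop("symptoms must be unique", call. = FALSE)
  }
  if (is.null(planted_effects) || nrow(as.data.frame(planted_effects)) == 0) {
    planted_effects <- tibble(symptom = character(), window = character(),
                              multiplier = numeric())
  } else {
    planted_effects <- as_tibble(planted_effects)
    stopifnot(all(c("symptom", "window", "multiplier") %in% names(planted_effects)))
    planted_effects <- planted_effects[c("symptom", "window", "multiplier")]
    planted_effects$symptom <- as.character(planted_effects$symptom)
    planted_effects$window <- as.character(planted_effects$window)
    planted_effects$multiplier <- as.numeric(planted_effects$multiplier)
    if (!all(planted_effects$window %in% PLANT_WINDOWS)) {
      stop("planted-effect windows must be one of: ",
           paste(PLANT_WINDOWS, collapse = ", "), call. = FALSE)
    }
    if (!all(planted_effects$symptom %in% symptoms)) {
      stop("planted-effect symptoms must appear in `symptoms`", call. = FALSE)
    }
    if (any(planted_effects$multiplier < 1)) {
      stop("planted multipliers must be >= 1", call. = FALSE)
    }
    if (anyDuplicated(planted_effects[c("symptom", "window")])) {
      stop("at most one planted effect per (symptom, window)", call. = FALSE)
    }
  }
  stopifnot(
    length(n_target_users) == 1, n_target_users >= 0,
    length(n_comparison_users) == 1, n_comparison_users >= 0,
    background_query_rate >= 0,
    symptom_base_prob >= 0, symptom_base_prob <= 1,
    meeting_prob >= 0, meeting_prob <= 1,
    background_click_prob >= 0, background_click_prob <= 1,
    all(c("AA", "NA", "BOTH") %in% names(group_weights)),
    all(group_weights >= 0), sum(group_weights) > 0
  )
  # per-symptom emission vocabulary (synonym phrases actually emitted)
  fixture <- read_lexicon(default_lexicon_path())
  vocab <- lapply(stats::setNames(symptoms, symptoms), function(s) {
    if (s %in% names(fixture$entries)) fixture$entries[[s]] else normalize_text(s)
  })
  structure(list(
    n_target_users = as.integer(n_target_users),
    n_comparison_users = as.integer(n_comparison_users),
    span_start = span_start, span_end = span_end,
    background_query_rate = as.numeric(background_query_rate),
    symptom_base_prob = as.numeric(symptom_base_prob),
    symptoms = symptoms,
    symptom_vocabulary = vocab,
    planted_effects = planted_effects,
    seed_vocabulary = as_tibble(seed_vocabulary),
    group_weights = stats::setNames(
      as.numeric(group_weights[c("AA", "NA", "BOTH")]),
      c("AA", "NA", "BOTH")
    ),
    meeting_prob = as.numeric(meeting_prob),
    background_click_prob = as.numeric(background_click_prob),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Null-model configuration (no planted effects)
#'
#' Convenience constructor for type-I-error studies: a configuration with the
#' stated number of symptoms, empty planted effects, and the generator's
#' documented defaults (500 target / 5000 comparison users, nine-month span,
#' background rate 0.1 queries per user-day, symptom base probability 0.01).
#'
#' @param n_symptoms number of symptoms emitted and tested (taken from the
#'   head of the packaged fixture lexicon).
#' @param seed integer RNG seed.
#' @param n_target_users,n_comparison_users cohort sizes.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
null_config <- function(n_symptoms = 20, seed = 1L,
                        n_target_users = 500, n_comparison_users = 5000, ...) {
  stopifnot(n_symptoms >= 1)
  all_symptoms <- lexicon_symptoms(read_lexicon(default_lexicon_path()))
  if (n_symptoms > length(all_symptoms)) {
    stop("n_symptoms exceeds the packaged fixture lexicon size (",
         length(all_symptoms), ")", call. = FALSE)
  }
  sim_config(
    n_target_users = n_target_users,
    n_comparison_users = n_comparison_users,
    symptoms = all_symptoms[seq_len(n_symptoms)],
    planted_effects = NULL,
    rng_seed = seed,
    ...
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d target + %d comparison users, %d symptoms, %d planted effect(s), seed %d\n",
    x$n_target_users, x$n_comparison_users, length(x$symptoms),
    nrow(x$planted_effects), x$rng_seed
  ))
  invisible(x)
}

#' Simulate a search log with known ground truth
#'
#' Generates one synthetic log under a [sim_config()]:
#' * every user emits background queries (per-day Poisson rate, nonsense
#'   vocabulary guaranteed not to match any symptom synonym);
#' * every user emits symptom queries as independent per-symptom per-day
#'   Bernoulli trials at `symptom_base_prob`; for target users the probability
#'   is multiplied by any planted multiplier on days falling in the stated
#'   window relative to their own index time (days are anchored at the index
#'   time for target users so each simulated day lies wholly inside one
#'   window);
#' * every target user issues one first seed query, with a click to a 12-step
#'   resource page, at a time uniform over the final calendar month of the
#'   span; users in the BOTH subgroup issue a second seed query for the other
#'   program shortly after; comparison users issue no seed queries.
#'
#' The generator is deterministic: identical configurations (including
#' `rng_seed`) give identical logs.
#'
#' @param config a [sim_config()].
#' @return list with elements `log` (a [search_log()]) and `truth` (a list
#'   with `users` — tibble of per-user role, subgroup, meeting flag and index
#'   time — and `planted_effects`, the configuration's effects echoed).
#' @export
simulate_logs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, simulate_logs_impl(config))
}

simulate_logs_impl <- function(config) {
  t0 <- as.numeric(config$span_start)
  t1 <- as.numeric(config$span_end)
  n_days <- floor((t1 - t0) / DAY)
  n_t <- config$n_target_users
  n_c <- config$n_comparison_users
  target_ids <- if (n_t > 0) sprintf("t%06d", seq_len(n_t)) else character(0)
  comparison_ids <- if (n_c > 0) sprintf("c%06d", seq_len(n_c)) else character(0)

  ## --- target index times, subgroups, seed queries -------------------------
  im_start <- max(as.numeric(month_floor(config$span_end - 1)), t0)
  index_time <- floor(stats::runif(n_t, im_start, t1))
  groups <- if (n_t > 0) {
    sample(c("AA", "NA", "BOTH"), n_t, replace = TRUE,
           prob = config$group_weights)
  } else character(0)
  meeting_first <- stats::runif(n_t) < config$meeting_prob

  vocab <- config$seed_vocabulary
  pick_seed_row <- function(program, meeting) {
    rows <- which(vocab$program == program & vocab$is_meeting == meeting)
    if (length(rows) == 0) rows <- which(vocab$program == program)
    if (length(rows) == 0) stop("seed vocabulary has no query for program ",
                                program, call. = FALSE)
    if (length(rows) == 1) rows else sample(rows, 1)
  }
  seed_events <- NULL
  if (n_t > 0) {
    first_program <- ifelse(groups == "BOTH",
                            sample(c("AA", "NA"), n_t, replace = TRUE),
                            groups)
    first_row <- vapply(seq_len(n_t), function(i) {
      pick_seed_row(first_program[i], meeting_first[i])
    }, integer(1))
    seed_events <- tibble(
      user_id = target_ids,
      timestamp = index_time,
      query_text = vocab$query_text[first_row],
      clicked_url = vocab$url[first_row]
    )
    both <- which(groups == "BOTH")
    if (length(both) > 0) {
      second_program <- ifelse(first_program[both] == "AA", "NA", "AA")
      second_row <- vapply(seq_along(both), function(i) {
        pick_seed_row(second_program[i], stats::runif(1) < config$meeting_prob)
      }, integer(1))
      gap <- floor(stats::runif(length(both)) *
                     pmin(DAY, t1 - index_time[both] - 1))
      seed_events <- dplyr::bind_rows(seed_events, tibble(
        user_id = target_ids[both],
        timestamp = index_time[both] + pmax(gap, 0),
        query_text = vocab$query_text[second_row],
        clicked_url = vocab$url[second_row]
      ))
    }
  }

  ## --- symptom queries ------------------------------------------------------
  # Per-symptom per-day Bernoulli emission. Days ("cells") are anchored at the
  # user's own index time for target users and at span_start for comparison
  # users, so each cell lies wholly inside one lead-up window. Because cells
  # are independent Bernoulli trials, we draw the number of hits per constant-
  # probability stratum as a binomial and place them uniformly without
  # replacement — exactly equivalent and much faster than per-cell draws.
  p0 <- config$symptom_base_prob
  effects <- config$planted_effects
  sym_events <- list()

  emit <- function(user_ids, anchor, cell_user, cell_k, cls) {
    # cls: integer class per cell (1 baseline, 2 distal, 3 middle,
    # 4 proximal, 5 post)
    strata <- split(seq_along(cls), cls)
    out <- vector("list", length(config$symptoms))
    for (si in seq_along(config$symptoms)) {
      s <- config$symptoms[si]
      mult <- c(1, 1, 1, 1, 1)
      if (nrow(effects) > 0) {
        eff <- effects[effects$symptom == s, , drop = FALSE]
        for (r in seq_len(nrow(eff))) {
          w <- eff$window[r]
          m <- eff$multiplier[r]
          if (w == "all") mult <- mult * m
          else mult[match(w, c("baseline", "distal", "middle", "proximal", "post"))] <-
              mult[match(w, c("baseline", "distal", "middle", "proximal", "post"))] * m
        }
      }
      picks <- integer(0)
      for (cl in names(strata)) {
        p <- min(p0 * mult[as.integer(cl)], 1)
        if (p <= 0) next
        n_cells <- length(strata[[cl]])
        m_hit <- stats::rbinom(1, n_cells, p)
        if (m_hit > 0) {
          picks <- c(picks, strata[[cl]][sample.int(n_cells, m_hit)])
        }
      }
      if (length(picks) > 0) {
        syns <- config$symptom_vocabulary[[s]]
        out[[si]] <- tibble(
          user_id = user_ids[cell_user[picks]],
          timestamp = anchor[cell_user[picks]] + cell_k[picks] * DAY +
            floor(stats::runif(length(picks)) * DAY),
          query_text = if (length(syns) == 1) rep(syns, length(picks))
                       else sample(syns, length(picks), replace = TRUE),
          clicked_url = NA_character_
        )
      }
    }
    dplyr::bind_rows(out)
  }

  if (n_t > 0 && length(config$symptoms) > 0) {
    k_before <- floor((index_time - t0) / DAY)
    k_after <- floor((t1 - index_time) / DAY)
    n_cells_u <- k_before + k_after
    cell_user <- rep(seq_len(n_t), n_cells_u)
    cell_k <- sequence(n_cells_u, from = -k_before, by = 1L)
    cls <- ifelse(cell_k >= 0, 5L,
                  ifelse(cell_k >= -7, 4L,
                         ifelse(cell_k >= -14, 3L,
                                ifelse(cell_k >= -30, 2L, 1L))))
    sym_events$target <- emit(target_ids, index_time, cell_user, cell_k, cls)
  }
  if (n_c > 0 && length(config$symptoms) > 0 && n_days > 0) {
    # all comparison cells share one probability stratum; avoid materializing
    # the full cell table
    syms <- config$symptoms
    out <- vector("list", length(syms))
    n_cells <- n_c * n_days
    for (si in seq_along(syms)) {
      m_hit <- stats::rbinom(1, n_cells, p0)
      if (m_hit > 0) {
        pick <- sample.int(n_cells, m_hit)
        u <- (pick - 1L) %/% n_days + 1L
        k <- (pick - 1L) %% n_days
        syns <- config$symptom_vocabulary[[syms[si]]]
        out[[si]] <- tibble(
          user_id = comparison_ids[u],
          timestamp = t0 + k * DAY + floor(stats::runif(m_hit) * DAY),
          query_text = if (length(syns) == 1) rep(syns, m_hit)
                       else sample(syns, m_hit, replace = TRUE),
          clicked_url = NA_character_
        )
      }
    }
    sym_events$comparison <- dplyr::bind_rows(out)
  }

  ## --- background queries ---------------------------------------------------
  all_ids <- c(target_ids, comparison_ids)
  bg_events <- NULL
  if (length(all_ids) > 0 && config$background_query_rate > 0) {
    span_days <- (t1 - t0) / DAY
    counts <- stats::rpois(length(all_ids),
                           config$background_query_rate * span_days)
    n_bg <- sum(counts)
    if (n_bg > 0) {
      clicked <- stats::runif(n_bg) < config$background_click_prob
      urls <- rep(NA_character_, n_bg)
      n_clicked <- sum(clicked)
      if (n_clicked > 0) {
        urls[clicked] <- paste0("https://pages.example.com/p",
                                sample.int(999L, n_clicked, replace = TRUE))
      }
      # precomposed two-word nonsense phrases (30 x 30 vocabulary)
      phrase <- paste(rep(BACKGROUND_WORDS, each = length(BACKGROUND_WORDS)),
                      BACKGROUND_WORDS)
      bg_events <- tibble(
        user_id = rep(all_ids, counts),
        timestamp = floor(stats::runif(n_bg, t0, t1)),
        query_text = phrase[sample.int(length(phrase), n_bg, replace = TRUE)],
        clicked_url = urls
      )
    }
  }

  events <- dplyr::bind_rows(seed_events, sym_events$target,
                             sym_events$comparison, bg_events)
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(user_id = character(), timestamp = numeric(),
                     query_text = character(), clicked_url = character())
  }
  events <- events[order(events$timestamp), , drop = FALSE]
  events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC",
                                 origin = "1970-01-01")
  log <- search_log(events, config$span_start, config$span_end)

  truth_users <- tibble(
    user_id = all_ids,
    role = rep(c("target", "comparison"), c(n_t, n_c)),
    group = c(groups, rep(NA_character_, n_c)),
    meeting_subsample = c(meeting_first, rep(NA, n_c)),
    index_time = as.POSIXct(c(index_time, rep(NA_real_, n_c)), tz = "UTC",
                            origin = "1970-01-01")
  )
  list(
    log = log,
    truth = list(users = truth_users, planted_effects = config$planted_effects)
  )
}

#' Lexicon matching a simulation's emitted symptoms
#'
#' Restriction of the symptom vocabulary a [sim_config()] emits to a
#' [symptom_lexicon()], so that a screen over simulated data tests exactly
#' the simulated symptoms (the Bonferroni divisor uses the number of symptoms
#' actually tested).
#'
#' @param config a [sim_config()].
#' @return a `symptom_lexicon` over `config$symptoms`.
#' @export
sim_lexicon <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  symptom_lexicon(config$symptom_vocabulary)
}

#' Write / read a ground-truth table
#'
#' Tab-separated per-user truth (role, subgroup, meeting flag, index time).
#' Values are written with empty fields for missing data so that the "NA"
#' subgroup label survives the round trip.
#'
#' @param truth the `truth` element returned by [simulate_logs()].
#' @param path output path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_ground_truth <- function(truth, path) {
  u <- truth$users
  u$index_time <- ifelse(is.na(u$index_time), "",
                         format_instant(u$index_time))
  utils::write.table(u, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
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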
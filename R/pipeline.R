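#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. Exactly one of `log` (a path
#' to a tab-separated query log, or a [search_log()] object) and `sim` (a
#' [sim_config()]) must be supplied.
#'
#' @param log input log path or `search_log`, or `NULL`.
#' @param sim a `sim_config`, or `NULL`.
#' @param lexicon_path symptom lexicon file; defaults to the packaged fixture.
#' @param seed_urls_path labeled seed-URL file; defaults to the packaged
#'   fixture.
#' @param out_dir output directory for result tables, or `NULL` to skip
#'   writing.
#' @param alpha family-wise significance level before Bonferroni correction.
#' @param min_users seed-query retention threshold (distinct users).
#' @param windows lead-up window table, default [window_specs()].
#' @param index_window optional explicit index window `(start, end)`.
#' @param yates apply the Yates continuity correction in the chi-square.
#' @param meeting_only restrict the target cohort to the meeting subsample.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(log = NULL, sim = NULL,
                            lexicon_path = default_lexicon_path(),
                            seed_urls_path = default_seed_urls_path(),
                            out_dir = NULL, alpha = 0.05, min_users = 50,
                            windows = window_specs(), index_window = NULL,
                            yates = FALSE, meeting_only = FALSE) {
  if (is.null(log) == is.null(sim)) {
    stop("exactly one of `log` and `sim` must be supplied", call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(alpha > 0, alpha <= 1, min_users >= 1)
  structure(list(
    log = log, sim = sim, lexicon_path = lexicon_path,
    seed_urls_path = seed_urls_path, out_dir = out_dir, alpha = alpha,
    min_users = min_users, windows = validate_windows(windows),
    index_window = if (is.null(index_window)) NULL else as_period(index_window),
    yates = isTRUE(yates), meeting_only = isTRUE(meeting_only)
  ), class = "pipeline_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full screening pipeline
#'
#' Executes, in order: input (read or simulate the log), seed-query discovery,
#' cohort identification and subgroup assignment, the between-group
#' probability-ratio screen, the time-lagged within-person temporal screen,
#' and the persistence classification. Progress is logged to stderr; results
#' never go to stderr. With an output directory set, writes `cohort.tsv`,
#' `ratios.tsv`, `windows.tsv`, `persistence.tsv` and `manifest.json`.
#' Identical configuration (including the simulation seed) gives identical
#' result tables.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: a list with `counts` (cohort
#'   tallies), `cohort`, `seeds`, `ratios`, `window_results`, `persistence`,
#'   `n_symptoms_tested`, `threshold`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  stage_msg("input", "loading inputs")
  if (!is.null(config$sim)) {
    sim <- simulate_logs(config$sim)
    log <- sim$log
    seed_used <- config$sim$rng_seed
  } else if (inherits(config$log, "search_log")) {
    log <- config$log
    seed_used <- NA_integer_
  } else {
    log <- read_query_log(config$log)
    seed_used <- NA_integer_
  }
  lexicon <- read_lexicon(config$lexicon_path)
  seed_urls <- read_seed_urls(config$seed_urls_path)
  stage_msg("input", "%d events, %d symptoms in lexicon",
            n_events(log), lexicon$size)

  stage_msg("seeds", "discovering seed queries (min_users = %d)",
            config$min_users)
  seeds <- discover_seed_queries(log, seed_urls, config$min_users)
  stage_msg("seeds", "%d seed queries retained", nrow(seeds))

  stage_msg("cohort", "identifying cohort")
  cohort <- identify_cohort(log, seeds, config$index_window)
  cohort <- assign_subgroups(cohort, log, seeds)
  if (config$meeting_only) {
    drop <- cohort$role == "target" & !isTRUE_vec(cohort$meeting_subsample)
    cohort$role[drop] <- "excluded"
    cohort$group[drop] <- NA_character_
    cohort$meeting_subsample[drop] <- NA
    cohort$index_time[drop] <- as.POSIXct(NA, tz = "UTC")
  }
  is_target <- cohort$role == "target"
  counts <- list(
    target = sum(is_target),
    AA = sum(cohort$group[is_target] == "AA"),
    `NA` = sum(cohort$group[is_target] == "NA"),
    BOTH = sum(cohort$group[is_target] == "BOTH"),
    meeting = sum(isTRUE_vec(cohort$meeting_subsample[is_target])),
    comparison = sum(cohort$role == "comparison"),
    excluded = sum(cohort$role == "excluded")
  )
  if (counts$AA + counts$`NA` + counts$BOTH != counts$target) {
    stop("cohort invariant violated: AA + NA + BOTH != target", call. = FALSE)
  }
  stage_msg("cohort", "%d target (AA %d / NA %d / BOTH %d), %d comparison, %d excluded",
            counts$target, counts$AA, counts$`NA`, counts$BOTH,
            counts$comparison, counts$excluded)

  ev <- log$events
  target_events <- ev[ev$user_id %in% cohort$user_id[is_target], , drop = FALSE]
  comparison_events <- ev[ev$user_id %in%
                            cohort$user_id[cohort$role == "comparison"], ,
                          drop = FALSE]
  n_windows <- nrow(config$windows)
  threshold <- bonferroni_threshold(config$alpha, lexicon$size, n_windows)

  empty_ratios <- tibble(symptom = character(), p_target = numeric(),
                         p_comparison = numeric(), ratio = numeric(),
                         rank = integer())
  empty_windows <- tibble(symptom = character(), window = character(),
                          A = integer(), B = integer(), C = integer(),
                          D = integer(), p_window = numeric(),
                          p_baseline = numeric(), chi_square = numeric(),
                          p_value = numeric(), significant = logical())
  if (counts$target == 0 || counts$comparison == 0) {
    stage_msg("screens", "cohort empty on one side; screens skipped")
    ratios <- empty_ratios
    window_results <- empty_windows
    persistence <- tibble(symptom = character(),
                          category = factor(character(),
                                            levels = PERSISTENCE_LEVELS),
                          windows = character())
  } else {
    stage_msg("screens", "between-group probability-ratio screen")
    ratios <- probability_ratio_screen(target_events, comparison_events,
                                       lexicon)
    stage_msg("screens", "time-lagged temporal screen")
    index_times <- cohort[is_target, c("user_id", "index_time")]
    window_results <- temporal_screen(
      target_events, index_times, lexicon, log$span_start,
      windows = config$windows, alpha = config$alpha, correct = config$yates
    )
    persistence <- classify_persistence(window_results)
    stage_msg("screens", "%d significant (symptom, window) pairs at threshold %.3g",
              sum(window_results$significant), threshold)
  }

  report <- structure(list(
    counts = counts,
    cohort = cohort,
    seeds = seeds,
    ratios = ratios,
    window_results = window_results,
    persistence = persistence,
    n_symptoms_tested = lexicon$size,
    threshold = threshold,
    provenance = list(
      package_version = as.character(utils::packageVersion("symptomlag")),
      rng_seed = seed_used,
      alpha = config$alpha,
      min_users = config$min_users,
      n_windows = n_windows,
      yates = config$yates,
      meeting_only = config$meeting_only,
      span = c(format_instant(log$span_start), format_instant(log$span_end)),
      input = if (!is.null(config$sim)) "simulated" else "file"
    )
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write a run report's tables to a directory
#'
#' Fixed layout: `cohort.tsv`, `ratios.tsv`, `windows.tsv`,
#' `persistence.tsv`, `manifest.json`.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain <- function(x, name) {
    x <- as.data.frame(x)
    for (col in names(x)) {
      if (is.factor(x[[col]])) x[[col]] <- as.character(x[[col]])
    }
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_cohort(report$cohort, file.path(out_dir, "cohort.tsv"))
  write_tsv_plain(report$ratios, "ratios.tsv")
  write_tsv_plain(report$window_results, "windows.tsv")
  write_tsv_plain(report$persistence, "persistence.tsv")
  manifest <- c(
    report$provenance,
    list(counts = report$counts,
         n_symptoms_tested = report$n_symptoms_tested,
         threshold = report$threshold)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable summary of a run report
#'
#' @param report a `run_report`.
#' @param top number of top-ratio symptoms to show.
#' @return character vector of summary lines (also used by the print method).
#' @export
summarize_report <- function(report, top = 10) {
  stopifnot(inherits(report, "run_report"))
  cn <- report$counts
  lines <- c(
    "== symptom query screen ==",
    sprintf("target users: %d (AA %d, NA %d, BOTH %d; meeting subsample %d)",
            cn$target, cn$AA, cn$`NA`, cn$BOTH, cn$meeting),
    sprintf("comparison users: %d; excluded (prior seekers): %d",
            cn$comparison, cn$excluded),
    sprintf("symptoms tested: %d; corrected threshold: %.3g",
            report$n_symptoms_tested, report$threshold)
  )
  if (cn$target == 0) {
    return(c(lines, "zero target users: screens not run"))
  }
  defined <- report$ratios[!is.na(report$ratios$ratio), , drop = FALSE]
  k <- min(top, nrow(defined))
  if (k > 0) {
    lines <- c(lines, sprintf("top %d probability ratios:", k),
               sprintf("  %2d. %-20s ratio %.2f (target %.4f vs comparison %.4f)",
                       defined$rank[seq_len(k)], defined$symptom[seq_len(k)],
                       defined$ratio[seq_len(k)], defined$p_target[seq_len(k)],
                       defined$p_comparison[seq_len(k)]))
  }
  per_cat <- split(as.character(report$persistence$symptom),
                   report$persistence$category)
  for (cat_name in setdiff(PERSISTENCE_LEVELS, "none")) {
    syms <- per_cat[[cat_name]]
    if (length(syms) > 0) {
      lines <- c(lines, sprintf("%s: %s", cat_name,
                                paste(syms, collapse = ", ")))
    }
  }
  n_none <- length(per_cat[["none"]])
  lines <- c(lines, sprintf("symptoms with no significant window: %d", n_none))
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(summarize_report(x), sep = "\n")
  invisible(x)
}

## ---- configuration files ---------------------------------------------------

sim_config_to_list <- function(sim) {
  list(
    n_target_users = sim$n_target_users,
    n_comparison_users = sim$n_comparison_users,
    span_start = format_instant(sim$span_start),
    span_end = format_instant(sim$span_end),
    background_query_rate = sim$background_query_rate,
    symptom_base_prob = sim$symptom_base_prob,
    symptoms = sim$symptoms,
    planted_effects = if (nrow(sim$planted_effects) == 0) list() else
      lapply(seq_len(nrow(sim$planted_effects)), function(i) {
        as.list(sim$planted_effects[i, ])
      }),
    seed_vocabulary = lapply(seq_len(nrow(sim$seed_vocabulary)), function(i) {
      as.list(sim$seed_vocabulary[i, ])
    }),
    group_weights = as.list(sim$group_weights),
    meeting_prob = sim$meeting_prob,
    background_click_prob = sim$background_click_prob,
    rng_seed = sim$rng_seed
  )
}

sim_config_from_list <- function(x) {
  pe <- if (length(x$planted_effects) == 0) NULL else
    dplyr::bind_rows(lapply(x$planted_effects, as_tibble))
  sv <- if (is.null(x$seed_vocabulary)) default_seed_vocabulary() else
    dplyr::bind_rows(lapply(x$seed_vocabulary, as_tibble))
  gw <- if (is.null(x$group_weights)) c(AA = 10522, `NA` = 1022, BOTH = 240)
        else unlist(x$group_weights)
  sim_config(
    n_target_users = x$n_target_users,
    n_comparison_users = x$n_comparison_users,
    span_start = x$span_start %||% "2016-11-01",
    span_end = x$span_end %||% "2017-08-01",
    background_query_rate = x$background_query_rate %||% 0.1,
    symptom_base_prob = x$symptom_base_prob %||% 0.01,
    symptoms = x$symptoms,
    planted_effects = pe,
    seed_vocabulary = sv,
    group_weights = gw,
    meeting_prob = x$meeting_prob %||% (3820 / 11784),
    background_click_prob = x$background_click_prob %||% 0.3,
    rng_seed = x$rng_seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a simulation configuration as YAML
#'
#' @param sim a [sim_config()].
#' @param path file path.
#' @return `path` invisibly (writer); a `sim_config` (reader).
#' @export
write_sim_config <- function(sim, path) {
  stopifnot(inherits(sim, "sim_config"))
  yaml::write_yaml(sim_config_to_list(sim), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  sim_config_from_list(yaml::read_yaml(path))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the input is
#' given either as `log: <path>` or as a `sim:` block with [sim_config()]
#' fields.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$sim)) sim_config_from_list(x$sim) else NULL
  pipeline_config(
    log = x$log, sim = sim,
    lexicon_path = x$lexicon_path %||% default_lexicon_path(),
    seed_urls_path = x$seed_urls_path %||% default_seed_urls_path(),
    out_dir = x$out_dir,
    alpha = x$alpha %||% 0.05,
    min_users = x$min_users %||% 50,
    yates = x$yates %||% FALSE,
    meeting_only = x$meeting_only %||% FALSE
  )
}
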
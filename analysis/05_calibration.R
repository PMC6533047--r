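#!/usr/bin/env Rscript
# Stage 5: calibration of the temporal screen by Monte-Carlo simulation,
# side by side in the two regimes (smaller replicate counts than the
# package's acceptance suite, which runs 200 null and 50 recovery
# replicates). Writes results/calibration.tsv.

library(symptomlag)

screen_sim <- function(cfg) {
  sim <- simulate_logs(cfg)
  seeds <- discover_seed_queries(sim$log,
                                 read_seed_urls(default_seed_urls_path()),
                                 min_users = 10)
  cohort <- identify_cohort(sim$log, seeds)
  idx <- cohort[cohort$role == "target", c("user_id", "index_time")]
  ev <- sim$log$events
  temporal_screen(ev[ev$user_id %in% idx$user_id, ], idx, sim_lexicon(cfg),
                  sim$log$span_start)
}

spans <- list(long = c("2016-11-01", "2017-08-01"),
              short = c("2017-06-02", "2017-08-01"))
symptoms <- lexicon_symptoms(read_lexicon(default_lexicon_path()))[1:20]
rows <- list()

for (regime in names(spans)) {
  sp <- spans[[regime]]

  n_null <- 20
  fp <- vapply(seq_len(n_null), function(i) {
    cfg <- sim_config(500, 2000, span_start = sp[1], span_end = sp[2],
                      symptoms = symptoms, rng_seed = 40000 + i)
    any(screen_sim(cfg)$significant)
  }, logical(1))

  n_rec <- 10
  rec <- vapply(seq_len(n_rec), function(i) {
    cfg <- sim_config(
      2000, 0, span_start = sp[1], span_end = sp[2], symptoms = symptoms,
      planted_effects = data.frame(symptom = "pyrosis", window = "proximal",
                                   multiplier = 8),
      rng_seed = 50000 + i
    )
    cls <- classify_persistence(screen_sim(cfg))
    as.character(cls$category[cls$symptom == "pyrosis"]) == "immediate"
  }, logical(1))

  rows[[regime]] <- data.frame(
    regime = regime,
    familywise_fp_rate = mean(fp), n_null = n_null,
    immediate_recovery_rate = mean(rec), n_recovery = n_rec
  )
  cat(sprintf(
    "%-5s regime: family-wise false-positive rate %.2f (%d nulls); x8 proximal recovery %.2f (%d replicates)\n",
    regime, mean(fp), n_null, mean(rec), n_rec
  ))
}

calib <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.table(calib, "results/calibration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("The long regime's zero recovery is structural: with a ~7-month baseline\n")
cat("and no duration normalization, the direction filter needs multiplier x\n")
cat("window-days > baseline-days (see the package vignette).\n")
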
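#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic study logs.
#
# Two regimes of the same generative model:
#   * long  — the nine-month observation span the study design mirrors
#             (Nov 2016 .. Aug 2017), index month July 2017;
#   * short — a 60-day span, where target users' baselines are 1-30 days
#             long, the regime in which the within-person screen has power
#             (see the package vignette on baseline saturation).
# Both plant a proximal x8 effect on pyrosis (heartburn) and a whole-history
# x10 elevation on urticaria (hives) in the target cohort.

library(symptomlag)

dir.create("results", showWarnings = FALSE)
symptoms <- lexicon_symptoms(read_lexicon(default_lexicon_path()))[1:20]
effects <- data.frame(
  symptom = c("pyrosis", "urticaria"),
  window = c("proximal", "all"),
  multiplier = c(8, 10)
)

make <- function(name, span_start, span_end, seed) {
  cfg <- sim_config(
    n_target_users = 500, n_comparison_users = 2000,
    span_start = span_start, span_end = span_end,
    symptoms = symptoms, planted_effects = effects, rng_seed = seed
  )
  sim <- simulate_logs(cfg)
  write_sim_config(cfg, sprintf("results/sim_%s.yaml", name))
  write_query_log(sim$log, sprintf("results/log_%s.tsv.gz", name))
  write_ground_truth(sim$truth, sprintf("results/truth_%s.tsv", name))
  cat(sprintf(
    "%-5s regime: %d events, %d users, span [%s, %s)\n",
    name, n_events(sim$log), nrow(sim$truth$users),
    format_instant(sim$log$span_start), format_instant(sim$log$span_end)
  ))
}

make("long", "2016-11-01", "2017-08-01", seed = 20260901L)
make("short", "2017-06-02", "2017-08-01", seed = 20260902L)
cat("wrote results/log_{long,short}.tsv.gz plus configs and ground truth\n")
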
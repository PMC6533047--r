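---
title: "Screening symptom queries in the lead-up to treatment-information seeking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening symptom queries in the lead-up to treatment-information seeking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomlag)
```

## The question and the data model

People who develop problematic alcohol or drug use often experience medical
symptoms — some severe, many mundane — before they ever look for treatment.
`symptomlag` implements a search-log analysis that asks: *which medical
symptoms do people query more often in the weeks before their first search
for 12-step program information (Alcoholics Anonymous / Narcotics
Anonymous)?*

The unit of data is a query event: an anonymous `user_id`, a UTC timestamp,
the query's free text, and optionally the URL clicked in response. A
`search_log` couples an event table with the half-open observation span
`[span_start, span_end)` it was collected in. All analyses are person-level:
a user either did or did not query a given symptom in a given period, no
matter how often they repeated it.

## Cohort construction

1. **Seed queries.** Queries are linked to treatment seeking empirically:
   a query string counts as a *seed query* when at least `min_users` distinct
   users issued it and clicked through to a known 12-step resource page.
   Each seed query is labeled AA or NA by the majority label of its clicked
   pages (BOTH on ties) and flagged as a *meeting* query when it contains the
   token "meeting". The published analysis used `min_users = 50` on a
   national search engine's logs; the parameter is configurable because
   synthetic logs are far smaller.
2. **Index time.** A user's index time is the timestamp of their first seed
   query. The *target cohort* consists of users whose index time falls in the
   final calendar month of the span and who made no seed query earlier.
3. **Exclusion.** Users with seed queries *before* the final month are
   excluded from both populations. The source method only removes them from
   the target group; we also keep them out of the comparison group because
   prior treatment seekers would contaminate the baseline population. This is
   a deliberate design choice, surfaced in the cohort table as the role
   `excluded`.
4. **Subgroups.** A target user is AA if all their index-window seed queries
   are AA-labeled, NA if all are NA-labeled, BOTH otherwise; the meeting
   subsample contains users whose *first* seed query was a meeting query.
   The pipeline enforces `AA + NA + BOTH == target` on every run.

## The two screens

**Between-group probability ratio.** For each lexicon symptom $s$,

$$ R_s = \frac{\Pr(\text{user queries } s \mid \text{target})}
             {\Pr(\text{user queries } s \mid \text{comparison})} $$

estimated as fractions of users with at least one matching query anywhere in
their history, ranked from highest to lowest. The comparison population is
*all users outside the target cohort* (exclusive comparison): with the target
cohort a tiny fraction of all users the two readings are numerically almost
identical, and the exclusive reading keeps the two groups disjoint. Symptoms
never queried by the comparison population have an undefined ratio and are
reported separately rather than silently given rank.

**Time-lagged within-person screen.** The 30 days before each user's index
time are partitioned into three disjoint half-open windows:
proximal $[-7, 0)$, middle $[-14, -7)$, distal $[-30, -14)$ days. (The
source description of the windows is internally inconsistent — the narrative
labels the lags "0-7, 7-14, 14-30 days" while the taxonomy's footnotes tie
the *last* time point to the immediately-before category; we adopt the
taxonomy reading, and all outputs carry window *labels*, never raw offsets,
to stay unambiguous.) For each symptom and window a person-level 2×2 table
is built over the evaluable target users:

|                   | queried symptom | did not |
|-------------------|-----------------|---------|
| in window         | A               | C       |
| in baseline       | B               | D       |

with the *baseline* defined as all activity strictly before index − 30 days,
common to all three windows, so the three tests use disjoint exposure
periods. Users whose baseline would be empty (observed fewer than 31 days
before index) are dropped and counted. The Pearson statistic

$$ X^2 = \frac{n\,(AD - BC)^2}{(A+B)(C+D)(A+C)(B+D)}, \qquad n = A+B+C+D $$

is referred to $\chi^2_1$; no continuity correction is applied by default
(none is named by the source method; a Yates flag is available). A
(symptom, window) pair is *significant* only when the window probability
$A/(A+C)$ exceeds the baseline probability $B/(B+D)$ **and** the p-value
clears the Bonferroni threshold $\alpha / (m \times 3)$, where $m$ is the
number of symptoms actually tested — always taken from the lexicon supplied,
never hard-coded (the published report divides by 152 × 3 although it
describes a 195-symptom lexicon; the package sidesteps that inconsistency by
construction). Degenerate tables (a zero margin) get statistic 0, p-value 1
and a flag.

**Persistence taxonomy.** Each symptom is classified by its set of
significant windows: `persistent` (all three), `near_persistent` (exactly
two), `immediate` (proximal only), `distal` (distal only), `middle_only`,
or `none` — a partition, enforced by construction.

**Paired-data caveat.** The 2×2 table compares two indicators measured on the
*same* users, yet the Pearson test treats the rows as independent samples; a
McNemar-style paired test would be more appropriate in principle. The screen
is implemented as printed in the source method, and this caveat is the
reason the package reports the table cells alongside the statistic.

## The synthetic-log generator

Real query logs of this kind are proprietary, so the package ships a seeded
generator (`sim_config()`, `simulate_logs()`) that produces logs with the
statistical structure the screens assume, plus a ground-truth ledger:

* **Background queries**: per-user Poisson with rate
  `background_query_rate` (default 0.1 queries per user-day), drawn from a
  fixed nonsense vocabulary that cannot match any lexicon synonym. The rate
  is deliberately modest; no published per-user rates exist for this setting,
  and background volume only exercises the plumbing, not the statistics.
* **Symptom queries**: independent per-symptom per-user-day Bernoulli trials
  at `symptom_base_prob` (default 0.01), so a user queries a symptom at most
  once per day — matching the person-level counting of the screens. Days are
  anchored at the user's own index time for target users, so each simulated
  day falls wholly inside one lead-up window and planted labels align exactly
  with detector labels. Comparison users emit symptoms at the same base rate
  (required for null ratios near 1). Emission is implemented as
  binomial-count-then-uniform-placement per constant-probability stratum,
  which is exactly equivalent to the per-day Bernoulli model and fast enough
  for hundreds of replicates.
* **Planted effects**: `(symptom, window, multiplier)` triples multiply the
  emission probability on target users' days in that window; the label
  `all` elevates the whole history (used to calibrate the between-group
  screen). Multipliers are ≥ 1 and probabilities are clamped at 1.
* **Seed queries**: each target user issues exactly one first seed query,
  with a click to a 12-step resource page, at a time uniform over the final
  calendar month; subgroup membership is sampled with weights mirroring the
  published cohort mix (AA : NA : BOTH = 10522 : 1022 : 240, meeting
  fraction 3820/11784); BOTH users issue a second seed query for the other
  program shortly after the first. Comparison users never issue seed
  queries.

What the generator does **not** emulate: realistic query language, weekday
and seasonal rhythms, user churn (every simulated user is observable over
the whole span), demographic structure, or multi-person browsers. Passing
calibration tests therefore demonstrates that the *statistical machinery* is
correct under its stated model — not that the pipeline would reproduce any
particular finding on real logs.

## Power, and the long-baseline saturation effect

The within-person screen inherits a deliberate asymmetry: the window (7 or
16 days) and the baseline (typically many months) are compared as raw
person-level probabilities without duration normalization. Writing $p$ for
the per-day query probability and $B$ for the baseline length in days, the
baseline indicator saturates as $1-(1-p)^B$, while a window of length $w$
elevated by a multiplier $k$ reaches $1-(1-kp)^w$. To first order the
direction filter $p_\text{window} > p_\text{baseline}$ requires $k w > B$:
**with a nine-month span ($B \approx 230$) no multiplier below ~33 on a
7-day window can ever be detected**, whatever the base rate. At the
generator defaults ($p = 0.01$), the baseline indicator sits near 0.90 and a
×8 proximal effect reaches only ≈ 0.45.

Two consequences, both verified by the package's own calibration suites:

* Under the null the screen is extremely conservative — the family-wise
  type-I rate over 200 replicates is far below the nominal 5% — so the
  ≤ 10% control criterion passes vacuously in this regime.
* A planted ×8 effect (whether proximal-only or in all three windows) is
  *never* recovered under the nine-month span at base probability 0.01: the
  recovery rate is 0, and the corresponding acceptance check is reported
  honestly as failing rather than being re-tuned.

The screen does have power exactly where its originating method found
signal: symptoms that are rare in a user's baseline relative to the lead-up
— new-onset complaints. The package demonstrates this in the *short-history
regime* (a 60-day span, where the baseline is 1–30 days long): there a ×8
proximal effect is detected and classified `immediate` essentially always.
`analysis/05_calibration.R` computes both regimes side by side. Real search
logs sit between these extremes: per-user symptom rates are orders of
magnitude below 0.01/day, but histories are also months long; the method's
sensitivity on real data is governed by the same $kw > B$ inequality.

## Numerical and design choices

* **Timestamps** are stored, simulated and serialized at whole-second
  resolution, ISO-8601 UTC; day boundaries are UTC. Log files carry a
  `#span` first line so the observation span round-trips exactly.
* **Ties** in timestamps keep stable input order everywhere (stable sorts
  only), making every pipeline stage deterministic.
* **Matching** is case-insensitive, punctuation-stripped, whole-word
  contiguous phrase containment — "rash" never fires inside "crash". One
  canonical symptom per synonym is enforced at load time; the canonical name
  is always its own synonym.
* **Normalization** of seed queries (lowercase, punctuation to spaces,
  collapsed whitespace) is what makes the "issued by ≥ `min_users` users"
  aggregation meaningful.
* **Degenerate inputs**: zero-margin tables are flagged, never significant;
  an empty target cohort short-circuits the screens and the report says so;
  a single-user cohort runs without error and yields nothing significant.
* **Problem sizes** used by the test and calibration suites (200 null
  replicates at 500/5000 users with 20 symptoms; 50 recovery replicates at
  2000 target users; 1000 random tables for the chi-square cross-check) were
  chosen once as the package's calibration design and are stated in the
  test code explicitly.

## Known limitations

* The Pearson test on paired person-level indicators (see above).
* No duration normalization between windows and baseline — the source
  method's choice, kept faithfully, with the power consequences analysed
  above and flagged in the screen's metadata
  (`attr(results, "duration_normalized")`).
* Bonferroni only; no FDR alternative is provided because the family is
  small and the originating analysis used Bonferroni.
* The packaged 40-symptom lexicon is a fixture for examples and simulation,
  not a clinical resource; real analyses must supply their own lexicon, and
  the Bonferroni divisor follows whatever lexicon is supplied.
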
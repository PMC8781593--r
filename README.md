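# ariburden

Acute respiratory infections (ARIs) are the most common illness of early
childhood, yet medical records miss the majority of episodes because most
never reach a doctor. Daily parent-kept symptom diaries capture the full
burden — if the stream of day-level symptom flags can be turned,
reproducibly, into discrete illness episodes. `ariburden` is an R package
for exactly that task: it ingests two-year daily symptom diaries from
infant birth cohorts, segments them into ARI episodes under an A/B-symptom
case definition, and computes the standard cohort burden statistics and
Poisson rate-ratio models. Because diary data of this kind are rarely
public, the package ships a seeded synthetic-cohort generator (covariates,
daily diaries, and the latent ground-truth episode table) so that every
pipeline stage is testable end to end.

It is written for epidemiologists and biostatisticians working with
longitudinal symptom-diary data in tidyverse style: every user-facing
function takes a data frame first and returns a tibble.

## The case definition and models

Each diary day records ten symptoms plus two doctor-diagnosis flags. Days
are classified as:

* **A-day** — at least one *A-symptom*: fever, wheezing, wet cough, or
  doctor-diagnosed pneumonia / otitis media;
* **B-pair day** — no A-symptom, but ≥ 2 *distinct* B-symptoms (dry cough,
  chills, sore throat, runny/blocked nose, increased need to sleep, loss of
  appetite, increased attachment);
* **single-B day**, **symptom-free day**, or **missing day** otherwise.

An ARI episode *begins* on an A-day or B-pair day. Any symptomatic day
(including a single B-symptom) keeps it open; **three consecutive
symptom-free days end it**, and the episode runs from its first to its last
symptomatic day. A single-B day outside any episode is an *orphan symptom
day*: it counts toward symptom burden but never starts an episode. Children
enter the analysis if their diary covers ≥ 98% of days 0–729 of life.

Per-child two-year episode counts `Y_i` are then modelled as

```
Y_i ~ Poisson(mu_i),   log mu_i = beta' x_i
```

with treatment-coded covariates (breastfeeding duration, daycare entry,
birth mode, birth term, sex, older siblings). Rate ratios are
`exp(beta)` with Wald 95% intervals, crude (one covariate at a time) and
adjusted (all jointly). Stratum comparisons of mean counts use Welch
two-sample confidence intervals.

The simulator draws episode onsets from a discrete-time daily hazard
`h0 · a(age) · s(month) · exp(beta' x)` — an age ramp over the first six
months, a winter-peaked seasonal sinusoid, and covariate effects — with
lognormal episode durations (mean 11 d, SD 5.8 d) and a guaranteed 3-day
symptom-free tail after each episode, so segmentation can recover the
latent truth exactly when missingness is off.

## Worked example

```r
library(ariburden)

cfg    <- sim_config(n_children = 288, seed = 2024)
cohort <- simulate_cohort(cfg)

inc   <- apply_inclusion(cohort$diary, cohort$covariates)
diary <- filter_included(cohort$diary, inc)
seg   <- segment_episodes(diary)
seg
#> ARI segmentation: 3814 episodes, 733 orphan symptom days, 288 children (missing rule: free)

counts <- episodes_per_child(seg) |> dplyr::filter(stratum == "0-24mo")
mean(counts$n_episodes)            # 13.2 episodes per child over two years
duration_summary(seg)
#> # A tibble: 1 × 8
#>   level       n  mean    sd median    q1    q3 quantile_type
#> 1 episode  3814  10.9  6.09      9     7    13             7

symptom_day_summary(diary)
#> Cohort burden: 208187 child-days, 42045 symptomatic (20.2%), 288 children

fit <- fit_poisson(counts[, c("child_id", "n_episodes")],
                   dplyr::filter(cohort$covariates, child_id %in% inc$included))
dplyr::filter(fit$table, covariate == "daycare_entry")
#>   covariate     level        is_reference crude_rr ... adj_rr adj_low adj_high
#> 1 daycare_entry none_by_24mo TRUE             1          1      NA      NA
#> 2 daycare_entry 0-12mo       FALSE            1.17       1.19    1.07    1.32
#> 3 daycare_entry 13-26mo      FALSE            1.19       1.20    1.08    1.34
```

Reading: this simulated cohort of 288 fully included children had 3,814
ARI episodes (13.2 per child; mean duration 10.9 days, median 9), was
symptomatic on 20.2% of observed child-days, and children entering daycare
had a ~1.2-fold adjusted rate of ARIs relative to children not in daycare
by age two. `tidy(fit)` and `glance(fit)` give broom-style views;
`autoplot(fit)` draws the forest plot, and
`autoplot(prevalence_by_month(diary, seg))` the seasonality profile.

The whole chain — simulate or ingest, filter, segment, summarise, regress —
is also available as one call, `run_pipeline(config, out_dir)`, which
writes machine-readable analogues of the cohort-description, burden,
episode-count and rate-ratio tables plus prevalence curves and a checksum
manifest; `inst/scripts/ari.R` wraps it for the shell.

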
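classify_one <- function(symptoms) {
  d <- make_diary(stats::setNames(list(symptoms), "0"))
  as.character(classify_days(d)$day_class)
}

test_that("day classification follows the A/B case definition", {
  expect_equal(classify_one("fever"), "A_DAY")
  expect_equal(classify_one("wheezing"), "A_DAY")
  expect_equal(classify_one("wet_cough"), "A_DAY")
  expect_equal(classify_one("dx_otitis_media"), "A_DAY")
  expect_equal(classify_one(c("runny_or_blocked_nose", "loss_of_appetite")),
               "B_PAIR_DAY")
  expect_equal(classify_one("dry_cough"), "SINGLE_B_DAY")
  expect_equal(classify_one(character()), "FREE")
  # A-precedence: fever + dry_cough is an A-day, not a B-anything
  expect_equal(classify_one(c("fever", "dry_cough")), "A_DAY")
})

test_that("severity grades of one symptom never count as two B-symptoms", {
  d <- make_diary(stats::setNames(list("dry_cough"), "0"))
  d$dry_cough <- 3L                      # severe, still one distinct symptom
  expect_equal(as.character(classify_days(d)$day_class), "SINGLE_B_DAY")
})

test_that("missing days classify as MISSING on the dense grid", {
  d <- make_diary(stats::setNames(list(character()), "0"))   # only day 0 present
  dense <- classify_days(materialize_days(d, observation_window(0, 2)))
  expect_equal(as.character(dense$day_class), c("FREE", "MISSING", "MISSING"))
})

test_that("segmentation reproduces hand-checked six-day diaries", {
  win <- observation_window(0, 5)

  # A-trigger, trailing B days, closed by three free days
  d1 <- full_diary(6, list(
    "0" = "fever",
    "1" = "runny_or_blocked_nose",
    "2" = "runny_or_blocked_nose"))
  seg1 <- expect_matches_oracle(d1, win)
  expect_equal(nrow(seg1$episodes), 1)
  expect_equal(seg1$episodes$start_day, 0L)
  expect_equal(seg1$episodes$last_symptom_day, 2L)
  expect_equal(seg1$episodes$duration_days, 3L)
  expect_equal(seg1$episodes$trigger, "A_symptom")
  expect_false(seg1$episodes$censored)

  # exactly three free days end the episode; a later A-day starts a new one
  d2 <- full_diary(6, list("0" = "fever", "4" = "fever"))
  seg2 <- expect_matches_oracle(d2, win)
  expect_equal(nrow(seg2$episodes), 2)
  expect_equal(seg2$episodes$start_day, c(0L, 4L))

  # two free days do not end it: one four-day episode
  d3 <- full_diary(6, list("0" = "fever", "3" = "fever"))
  seg3 <- expect_matches_oracle(d3, win)
  expect_equal(nrow(seg3$episodes), 1)
  expect_equal(seg3$episodes$duration_days, 4L)

  # an isolated single B-symptom never starts an episode
  d4 <- full_diary(6, list("0" = "dry_cough"))
  seg4 <- expect_matches_oracle(d4, win)
  expect_equal(nrow(seg4$episodes), 0)
  expect_equal(seg4$orphans$day_of_life, 0L)
  expect_equal(seg4$orphans$symptom, "dry_cough")

  # a B-pair opens an episode that absorbs a following single B day
  d5 <- full_diary(6, list(
    "1" = c("chills", "sore_throat"),
    "2" = "sore_throat"))
  seg5 <- expect_matches_oracle(d5, win)
  expect_equal(seg5$episodes$trigger, "B_pair")
  expect_equal(seg5$episodes$n_symptom_days, 2L)
  expect_equal(nrow(seg5$orphans), 0)
})

test_that("an episode open at the window end is censored at its last symptomatic day", {
  win <- observation_window(0, 9)
  d <- full_diary(10, list("7" = "fever", "8" = "dry_cough"))
  seg <- expect_matches_oracle(d, win)
  expect_true(seg$episodes$censored)
  expect_equal(seg$episodes$last_symptom_day, 8L)
  # with three free days observed after, not censored
  d2 <- full_diary(10, list("5" = "fever", "6" = "dry_cough"))
  seg2 <- expect_matches_oracle(d2, win)
  expect_false(seg2$episodes$censored)
})

test_that("missing-day rule: free counts toward termination, pause does not", {
  win <- observation_window(0, 7)
  # fever d0, days 1-3 missing, fever d4
  days <- list("0" = "fever", "4" = "fever",
               "5" = character(), "6" = character(), "7" = character())
  d <- make_diary(days)
  free_rule <- segment_episodes(d, win, missing_rule = "free")
  expect_equal(nrow(free_rule$episodes), 2)      # missing run of 3 closes it
  pause_rule <- segment_episodes(d, win, missing_rule = "pause")
  expect_equal(nrow(pause_rule$episodes), 1)     # counter paused, one episode
  expect_equal(pause_rule$episodes$last_symptom_day, 4L)
  # oracle agrees under both rules
  expect_matches_oracle(d, win, "free")
  expect_matches_oracle(d, win, "pause")
})

test_that("segmentation agrees exactly with the brute-force oracle on random diaries", {
  withr::local_seed(42)
  win <- observation_window(0, 59)
  for (i in 1:200) {
    d <- random_diary(60, p_symptom = runif(1, 0.02, 0.15), p_missing = 0.1)
    rule <- if (i %% 2 == 0) "free" else "pause"
    expect_matches_oracle(d, win, rule)
  }
})

test_that("every symptomatic day is attributed to exactly one episode or orphan day", {
  withr::local_seed(7)
  win <- observation_window(0, 59)
  for (i in 1:25) {
    d <- random_diary(60, p_symptom = 0.1, p_missing = 0.05)
    seg <- segment_episodes(d, win)
    cls <- classify_days(materialize_days(d, win))
    symptomatic_days <- cls$day_of_life[
      cls$day_class %in% c("A_DAY", "B_PAIR_DAY", "SINGLE_B_DAY")]
    ep_days <- unlist(purrr::map2(seg$episodes$start_day,
                                  seg$episodes$last_symptom_day, seq.int))
    ep_sym_days <- intersect(ep_days, symptomatic_days)
    covered <- c(ep_sym_days, seg$orphans$day_of_life)
    expect_setequal(covered, symptomatic_days)
    expect_equal(anyDuplicated(covered), 0)
  }
})

test_that("widening an inter-episode gap never merges; shrinking below 3 free days merges", {
  win9 <- observation_window(0, 9)
  merged <- full_diary(10, list("0" = "fever", "3" = "fever"))
  split <- full_diary(10, list("0" = "fever", "4" = "fever"))
  expect_equal(nrow(segment_episodes(merged, win9)$episodes), 1)
  expect_equal(nrow(segment_episodes(split, win9)$episodes), 2)
  wider <- full_diary(10, list("0" = "fever", "8" = "fever"))
  expect_equal(nrow(segment_episodes(wider, win9)$episodes), 2)
})

test_that("episode counts are assigned to strata by start day and conserved", {
  # starts d10 (0-6mo) and d400 (13-18mo); the second spans into nothing else
  d <- full_diary(730, list("10" = "fever", "360" = "fever",
                            "361" = "fever", "362" = "fever",
                            "363" = "fever", "364" = "fever",
                            "365" = "fever", "366" = "fever",
                            "367" = "fever", "368" = "fever",
                            "369" = "fever", "370" = "fever",
                            "400" = "fever"))
  seg <- segment_episodes(d)
  counts <- episodes_per_child(seg)
  get <- function(s) counts$n_episodes[counts$stratum == s]
  # the episode starting d360 straddles the year boundary but counts in 0-12mo
  expect_equal(get("0-12mo"), 2L)
  expect_equal(get("13-24mo"), 1L)
  expect_equal(get("0-24mo"), 3L)
  expect_equal(get("0-6mo") + get("7-12mo"), get("0-12mo"))
  expect_equal(get("13-18mo") + get("19-24mo"), get("13-24mo"))
})

test_that("per-stratum counts sum to the total for every simulated child", {
  cfg <- sim_config(n_children = 150, seed = 9)
  co <- suppressMessages(simulate_cohort(cfg))
  counts <- episodes_per_child(segment_episodes(co$diary))
  wide <- tidyr::pivot_wider(counts, names_from = "stratum",
                             values_from = "n_episodes")
  expect_equal(wide$`0-6mo` + wide$`7-12mo` + wide$`13-18mo` + wide$`19-24mo`,
               wide$`0-24mo`)
  expect_equal(wide$`0-12mo` + wide$`13-24mo`, wide$`0-24mo`)
})

test_that("age at first episode is the earliest start, censored when none", {
  d <- full_diary(730, list("91" = "fever", "200" = "fever"))
  covs <- dplyr::bind_rows(make_covariates("c1"), make_covariates("c2"))
  seg <- segment_episodes(d, children = covs$child_id)
  first <- age_at_first_episode(seg)
  expect_equal(first$first_episode_day[first$child_id == "c1"], 91L)
  expect_true(first$censored[first$child_id == "c2"])
  # cohort median matches a direct sort-and-pick oracle on simulated data
  cfg <- sim_config(n_children = 100, seed = 3)
  co <- suppressMessages(simulate_cohort(cfg))
  seg2 <- segment_episodes(co$diary)
  med <- median(age_at_first_episode(seg2)$first_episode_day, na.rm = TRUE)
  oracle_med <- median(
    dplyr::summarise(dplyr::group_by(seg2$episodes, child_id),
                     m = min(start_day))$m)
  expect_equal(med, oracle_med)
})

test_that("duration summaries use the linear-interpolation quantile convention", {
  ep3 <- tibble::tibble(child_id = "x", start_day = c(0L, 10L, 20L),
                        last_symptom_day = c(2L, 12L, 22L),
                        duration_days = c(3L, 3L, 3L),
                        trigger = "A_symptom", censored = FALSE,
                        n_symptom_days = 3L)
  s <- duration_summary(ep3)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_equal(s$median, 3)

  ep2 <- ep3[1:2, ]
  ep2$duration_days <- c(2L, 4L)
  s2 <- duration_summary(ep2)
  expect_equal(s2$mean, 3)
  expect_equal(s2$median, 3)
  expect_equal(s2$q1, quantile(c(2, 4), 0.25, names = FALSE, type = 7))

  # child_mean level averages within child first
  ep_mix <- dplyr::bind_rows(
    dplyr::mutate(ep3, child_id = "a"),
    dplyr::mutate(ep2, child_id = "b"))
  sc <- duration_summary(ep_mix, level = "child_mean")
  expect_equal(sc$n, 2L)
  expect_equal(sc$mean, mean(c(3, 3)))
})
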
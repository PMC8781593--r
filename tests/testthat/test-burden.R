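test_that("symptom-day totals count days, not symptom tokens", {
  sympt <- list(
    "0" = c("fever", "dry_cough"),                     # 1 day, fever + cough
    "5" = "runny_or_blocked_nose",
    "10" = c("wet_cough", "dry_cough")                 # both coughs = 1 cough day
  )
  d <- full_diary(730, sympt)
  b <- symptom_day_summary(d)
  expect_equal(b$cohort$child_days, 730L)
  expect_equal(b$cohort$symptomatic_days, 3L)
  expect_equal(b$cohort$fraction_symptomatic, 3 / 730)
  pc <- b$per_child
  expect_equal(pc$overall, 3L)
  expect_equal(pc$fever, 1L)
  expect_equal(pc$cough, 2L)          # wet or dry, per day
  expect_equal(pc$dry_cough, 2L)
  expect_equal(pc$runny_or_blocked_nose, 1L)
})

test_that("per-stratum symptom days sum to the overall total per child", {
  cfg <- sim_config(n_children = 60, seed = 12)
  co <- suppressMessages(simulate_cohort(cfg))
  b <- symptom_day_summary(co$diary)
  pc <- b$per_child
  expect_equal(pc$`0-6mo` + pc$`7-12mo` + pc$`13-18mo` + pc$`19-24mo`,
               pc$overall)
  # cohort fraction equals an independent group-and-count oracle
  oracle <- co$diary |>
    dplyr::mutate(sympt = rowSums(dplyr::across(dplyr::all_of(symptom_codes()))) > 0) |>
    dplyr::summarise(f = sum(sympt) / dplyr::n())
  expect_equal(b$cohort$fraction_symptomatic, oracle$f)
  # no per-symptom count can exceed the child's observed days
  expect_true(all(pc$overall <= 730))
})

test_that("percentile curves are valid ECDFs", {
  pc <- tibble::tibble(child_id = c("a", "b", "c"), overall = c(0L, 10L, 20L))
  curves <- percentile_curves(pc, "overall")
  expect_equal(curves$days, c(0, 10, 20))
  expect_equal(curves$cdf, c(1 / 3, 2 / 3, 1))

  all_equal <- tibble::tibble(child_id = c("a", "b"), overall = c(5L, 5L))
  step <- percentile_curves(all_equal, "overall")
  expect_equal(step$cdf, 1)

  cfg <- sim_config(n_children = 40, seed = 21)
  co <- suppressMessages(simulate_cohort(cfg))
  curves2 <- percentile_curves(symptom_day_summary(co$diary))
  for (m in unique(curves2$measure)) {
    cdf <- curves2$cdf[curves2$measure == m]
    expect_true(all(diff(cdf) >= 0))
    expect_equal(max(cdf), 1)
    expect_true(all(cdf >= 0 & cdf <= 1))
  }
})

test_that("prevalence is in-episode child-days over observed child-days", {
  win <- observation_window(0, 9)
  covs <- dplyr::bind_rows(make_covariates("c1"), make_covariates("c2"))
  d <- dplyr::bind_rows(
    full_diary(10, list("2" = "fever", "3" = "fever"), child_id = "c1"),
    full_diary(10, list("2" = "wet_cough"), child_id = "c2"))
  seg <- segment_episodes(d, win)
  prev <- prevalence_by_day(d, seg)
  expect_equal(prev$proportion[prev$value == 2], 1.0)   # both in episode
  expect_equal(prev$proportion[prev$value == 3], 0.5)
  expect_equal(prev$proportion[prev$value == 9], 0)
  expect_true(all(prev$proportion >= 0 & prev$proportion <= 1))
  expect_true(all(prev$denominator > 0))

  # no episodes -> zero everywhere
  d0 <- full_diary(10, child_id = "c3")
  seg0 <- segment_episodes(d0, win)
  expect_true(all(prevalence_by_day(d0, seg0)$proportion == 0))
})

test_that("monthly prevalence reflects a winter-peaked onset hazard", {
  cfg <- sim_config(n_children = 250, seed = 33, missing_rate = 0.01)
  co <- suppressMessages(simulate_cohort(cfg))
  seg <- segment_episodes(co$diary)
  prev <- prevalence_by_month(co$diary, seg)
  expect_equal(nrow(prev), 12)
  winter <- mean(prev$proportion[prev$month %in% c("Dec", "Jan", "Feb")])
  summer <- mean(prev$proportion[prev$month %in% c("Jun", "Jul", "Aug")])
  expect_gt(winter, summer)
})

test_that("Welch mean differences reproduce printed group-mean identities", {
  # per-child counts constructed to have group means exactly 15.8 and 13.1
  counts <- tibble::tibble(
    child_id = sprintf("k%02d", 1:40),
    n_episodes = c(rep(15, 10), rep(16.6, 10),   # mean 15.8 (n = 20)
                   rep(13, 10), rep(13.2, 10)))  # mean 13.1 (n = 20)
  covs <- dplyr::bind_rows(purrr::map(counts$child_id, make_covariates))
  covs$older_siblings <- factor(rep(c("2+", "0"), each = 20),
                                levels = c("0", "1", "2+"))
  res <- strata_mean_difference(counts, covs,
                                variables = c(older_siblings = "0"))
  expect_equal(res$mean[res$level == "2+"], 15.8)
  expect_equal(res$mean[res$level == "0"], 13.1)
  expect_equal(res$difference[res$level == "2+"], 15.8 - 13.1)
  expect_true(res$is_reference[res$level == "0"])

  # Welch CI agrees with a direct t.test call
  tt <- t.test(counts$n_episodes[1:20], counts$n_episodes[21:40])
  expect_equal(res$conf_low[res$level == "2+"], tt$conf.int[1])
  expect_equal(res$conf_high[res$level == "2+"], tt$conf.int[2])
})

test_that("identical groups give zero difference with a CI spanning zero", {
  counts <- tibble::tibble(child_id = sprintf("k%02d", 1:6),
                           n_episodes = rep(c(1L, 2L, 3L), 2))
  covs <- dplyr::bind_rows(purrr::map(counts$child_id, make_covariates))
  covs$sex <- factor(rep(c("male", "female"), each = 3),
                     levels = c("male", "female"))
  res <- strata_mean_difference(counts, covs, variables = c(sex = "female"))
  expect_equal(res$difference[res$level == "male"], 0)
  expect_lt(res$conf_low[res$level == "male"], 0)
  expect_gt(res$conf_high[res$level == "male"], 0)
})

test_that("Welch interval coverage is near nominal on normal data", {
  withr::local_seed(2024)
  true_diff <- 3
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    g1 <- rnorm(200, 13, 5)
    g0 <- rnorm(200, 10, 5)
    ci <- t.test(g1, g0)$conf.int
    if (ci[1] <= true_diff && true_diff <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.93)
  expect_lte(hits / n_rep, 0.985)
})
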
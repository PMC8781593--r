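# Independent brute-force segmentation oracle: a literal day-by-day state
# machine with its own symptom classification, kept deliberately naive and
# separate from the package's run-length implementation.

oracle_classify_row <- function(row) {
  a <- c("fever", "wheezing", "wet_cough", "dx_pneumonia", "dx_otitis_media")
  b <- c("dry_cough", "chills", "sore_throat", "runny_or_blocked_nose",
         "increased_need_to_sleep", "loss_of_appetite", "increased_attachment")
  if (!isTRUE(row$entry_present)) return("MISSING")
  if (any(unlist(row[a]) > 0)) return("A_DAY")
  nb <- sum(unlist(row[b]) > 0)
  if (nb >= 2) return("B_PAIR_DAY")
  if (nb == 1) return("SINGLE_B_DAY")
  "FREE"
}

# diary: validated rows of one child; returns list(episodes, orphan_days)
oracle_segment <- function(diary, window = observation_window(),
                           missing_rule = "free") {
  days <- seq(window$start_day, window$end_day)
  cls <- character(length(days))
  for (i in seq_along(days)) {
    row <- diary[diary$day_of_life == days[i], ]
    cls[i] <- if (nrow(row) == 1) oracle_classify_row(row) else "MISSING"
  }
  if (missing_rule == "pause") {
    keep <- cls != "MISSING"
    cls <- cls[keep]; days <- days[keep]
  }

  episodes <- list(); orphans <- integer()
  in_ep <- FALSE; free_run <- 0L
  start <- NA_integer_; last <- NA_integer_; nsym <- 0L; trig <- NA_character_
  close_ep <- function(censored) {
    episodes[[length(episodes) + 1L]] <<- tibble::tibble(
      start_day = start, last_symptom_day = last,
      duration_days = last - start + 1L, trigger = trig,
      censored = censored, n_symptom_days = nsym)
  }
  for (i in seq_along(days)) {
    c_i <- cls[i]
    symptomatic <- c_i %in% c("A_DAY", "B_PAIR_DAY", "SINGLE_B_DAY")
    if (!in_ep) {
      if (c_i %in% c("A_DAY", "B_PAIR_DAY")) {
        in_ep <- TRUE; start <- days[i]; last <- days[i]; nsym <- 1L
        trig <- if (c_i == "A_DAY") "A_symptom" else "B_pair"
        free_run <- 0L
      } else if (c_i == "SINGLE_B_DAY") {
        orphans <- c(orphans, days[i])
      }
    } else {
      if (symptomatic) {
        last <- days[i]; nsym <- nsym + 1L; free_run <- 0L
      } else {
        free_run <- free_run + 1L
        if (free_run == 3L) {
          close_ep(FALSE); in_ep <- FALSE; free_run <- 0L
        }
      }
    }
  }
  if (in_ep) close_ep(TRUE)
  list(
    episodes = if (length(episodes)) dplyr::bind_rows(episodes) else
      tibble::tibble(start_day = integer(), last_symptom_day = integer(),
                     duration_days = integer(), trigger = character(),
                     censored = logical(), n_symptom_days = integer()),
    orphan_days = orphans
  )
}

# compare one child's implementation output against the oracle
expect_matches_oracle <- function(diary, window = observation_window(),
                                  missing_rule = "free") {
  seg <- segment_episodes(diary, window, missing_rule = missing_rule)
  orc <- oracle_segment(diary, window, missing_rule = missing_rule)
  imp <- seg$episodes[, c("start_day", "last_symptom_day", "duration_days",
                          "trigger", "censored", "n_symptom_days")]
  expect_equal(as.data.frame(imp), as.data.frame(orc$episodes))
  expect_equal(sort(seg$orphans$day_of_life), sort(orc$orphan_days))
  invisible(seg)
}
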
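# ARI episode segmentation.
#
# Case definition: an episode begins on a day with at least one A-symptom
# (fever, wheezing, wet cough, or a doctor-diagnosed pneumonia / otitis
# media) or a day with two distinct B-symptoms. Once open, any symptomatic
# day (including a single B-symptom) keeps it open; three consecutive
# symptom-free days end it, and the episode's last day is its final
# symptomatic day. A single B-symptom day outside any episode is an orphan
# symptom day: it counts toward symptom burden but never starts an episode.

#' Classify diary days under the A/B case definition
#'
#' Appends a `day_class` factor: `A_DAY` (>= 1 A-symptom, including
#' diagnosis flags; takes precedence), `B_PAIR_DAY` (>= 2 distinct
#' B-symptoms, no A), `SINGLE_B_DAY` (exactly 1 B-symptom, no A), `FREE`
#' (entry recorded, no symptoms), `MISSING` (no diary entry). Distinctness
#' is over symptom codes, so severity grades of one symptom never count
#' twice.
#'
#' @param diary Diary tibble with the ten symptom columns, the two diagnosis
#'   flags and `entry_present` (e.g. from [read_diary()] or
#'   [materialize_days()]).
#' @return `diary` with a `day_class` column appended.
#' @export
#' @examples
#' day <- tibble::tibble(child_id = "c1", day_of_life = 0L, entry_present = TRUE)
#' for (s in symptom_codes()) day[[s]] <- 0L
#' day$dx_pneumonia <- day$dx_otitis_media <- 0L
#' day$fever <- 1L
#' classify_days(day)$day_class
classify_days <- function(diary) {
  a_mat <- as.matrix(diary[, c(ARI_A_SYMPTOMS, ARI_DX_FLAGS), drop = FALSE]) > 0
  b_mat <- as.matrix(diary[, ARI_B_SYMPTOMS, drop = FALSE]) > 0
  any_a <- rowSums(a_mat) > 0
  n_b <- rowSums(b_mat)
  cls <- dplyr::case_when(
    !diary$entry_present ~ "MISSING",
    any_a ~ "A_DAY",
    n_b >= 2 ~ "B_PAIR_DAY",
    n_b == 1 ~ "SINGLE_B_DAY",
    TRUE ~ "FREE"
  )
  diary$day_class <- factor(cls, levels = DAY_CLASSES)
  diary
}

# Segment one child's dense, ordered day sequence. Run-length walk over the
# symptomatic indicator; under the "pause" missing rule, MISSING days are
# removed from the sequence first so that only recorded symptom-free days
# advance the 3-day termination counter.
segment_child <- function(day_class, day_of_life, missing_rule) {
  if (missing_rule == "pause") {
    keep <- day_class != "MISSING"
    day_class <- day_class[keep]
    day_of_life <- day_of_life[keep]
  }
  sym <- day_class %in% c("A_DAY", "B_PAIR_DAY", "SINGLE_B_DAY")
  qual <- day_class %in% c("A_DAY", "B_PAIR_DAY")

  runs <- rle(sym)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  ep_start <- integer(); ep_last <- integer(); ep_trig <- character()
  ep_nsym <- integer(); ep_cens <- logical()
  orphan_idx <- integer()

  in_ep <- FALSE
  cur_start <- NA_integer_; cur_trig <- NA_character_
  cur_last <- NA_integer_; cur_nsym <- 0L

  n_runs <- length(runs$lengths)
  for (r in seq_len(n_runs)) {
    i0 <- starts[r]; i1 <- ends[r]
    if (runs$values[r]) {                      # symptomatic run
      if (!in_ep) {
        q <- which(qual[i0:i1])
        if (length(q)) {
          qi <- i0 + q[1L] - 1L
          if (qi > i0) orphan_idx <- c(orphan_idx, i0:(qi - 1L))
          in_ep <- TRUE
          cur_start <- qi
          cur_trig <- if (day_class[qi] == "A_DAY") "A_symptom" else "B_pair"
          cur_last <- i1
          cur_nsym <- i1 - qi + 1L
        } else {
          orphan_idx <- c(orphan_idx, i0:i1)   # run of isolated B-days
        }
      } else {
        cur_last <- i1
        cur_nsym <- cur_nsym + (i1 - i0 + 1L)
      }
    } else {                                   # symptom-free (or missing) run
      if (in_ep && runs$lengths[r] >= 3L) {
        ep_start <- c(ep_start, cur_start); ep_last <- c(ep_last, cur_last)
        ep_trig <- c(ep_trig, cur_trig); ep_nsym <- c(ep_nsym, cur_nsym)
        ep_cens <- c(ep_cens, FALSE)
        in_ep <- FALSE
      }
    }
  }
  if (in_ep) {                                 # open at window end
    ep_start <- c(ep_start, cur_start); ep_last <- c(ep_last, cur_last)
    ep_trig <- c(ep_trig, cur_trig); ep_nsym <- c(ep_nsym, cur_nsym)
    ep_cens <- c(ep_cens, TRUE)
  }

  list(
    episodes = tibble::tibble(
      start_day = day_of_life[ep_start],
      last_symptom_day = day_of_life[ep_last],
      duration_days = day_of_life[ep_last] - day_of_life[ep_start] + 1L,
      trigger = ep_trig,
      censored = ep_cens,
      n_symptom_days = ep_nsym
    ),
    orphans = tibble::tibble(
      day_of_life = day_of_life[orphan_idx],
      symptom = vapply(orphan_idx, function(i) NA_character_, character(1))
    )
  )
}

#' Segment diaries into ARI episodes
#'
#' Runs the case-definition state machine over each child's dense day
#' sequence: a qualifying day (A-symptom, or two distinct B-symptoms) opens
#' an episode; any symptomatic day keeps it open; three consecutive
#' symptom-free days close it at the last symptomatic day. Isolated single
#' B-symptom days outside episodes are returned separately as orphan symptom
#' days. An episode still open at the window end is closed at its last
#' symptomatic day and flagged `censored`.
#'
#' @param diary Validated diary tibble (present rows only; missing days are
#'   materialized internally).
#' @param window An [observation_window()].
#' @param missing_rule How a missing diary day interacts with the 3-day
#'   termination counter: `"free"` (default; counts as symptom-free --
#'   appropriate for the >= 98%-complete cohort) or `"pause"` (ignored: only
#'   recorded symptom-free days advance the counter).
#' @param children Optional child-id universe (children with no diary rows
#'   yield no episodes).
#' @return A list with class `"ari_segmentation"`: `episodes` (tibble
#'   `child_id`, `start_day`, `last_symptom_day`, `duration_days`, `trigger`
#'   in `A_symptom`/`B_pair`, `censored`, `n_symptom_days`), `orphans`
#'   (tibble `child_id`, `day_of_life`, `symptom`), plus the `window`,
#'   `missing_rule` and `children` used.
#' @export
segment_episodes <- function(diary, window = observation_window(),
                             missing_rule = c("free", "pause"),
                             children = NULL) {
  missing_rule <- match.arg(missing_rule)
  dup <- duplicated(diary[c("child_id", "day_of_life")])
  if (any(dup)) {
    abort(paste0("duplicate child-day rows: ",
                 paste(utils::head(
                   paste(diary$child_id[dup], diary$day_of_life[dup]), 10L),
                   collapse = "; ")))
  }
  children <- as.character(children %||% sort(unique(diary$child_id)))
  dense <- classify_days(materialize_days(diary, window, children))
  dense <- dplyr::arrange(dense, .data$child_id, .data$day_of_life)

  # single-B days carry exactly one B-symptom; record which
  b_mat <- as.matrix(dense[, ARI_B_SYMPTOMS, drop = FALSE]) > 0
  single_b <- max.col(b_mat, ties.method = "first")
  single_b_name <- ARI_B_SYMPTOMS[single_b]

  parts <- split(seq_len(nrow(dense)), dense$child_id)
  res <- purrr::map(parts, function(idx) {
    out <- segment_child(as.character(dense$day_class[idx]),
                         dense$day_of_life[idx], missing_rule)
    if (nrow(out$orphans)) {
      m <- match(out$orphans$day_of_life, dense$day_of_life[idx])
      out$orphans$symptom <- single_b_name[idx][m]
    }
    out
  })

  episodes <- dplyr::bind_rows(purrr::map(res, "episodes"), .id = "child_id")
  orphans <- dplyr::bind_rows(purrr::map(res, "orphans"), .id = "child_id")
  if (!nrow(episodes)) {
    episodes <- tibble::tibble(child_id = character(), start_day = integer(),
                               last_symptom_day = integer(),
                               duration_days = integer(), trigger = character(),
                               censored = logical(), n_symptom_days = integer())
  }
  if (!nrow(orphans)) {
    orphans <- tibble::tibble(child_id = character(), day_of_life = integer(),
                              symptom = character())
  }
  structure(
    list(episodes = tibble::as_tibble(episodes),
         orphans = tibble::as_tibble(orphans),
         window = window, missing_rule = missing_rule, children = children),
    class = "ari_segmentation"
  )
}

#' @export
print.ari_segmentation <- function(x, ...) {
  cat(sprintf(
    "ARI segmentation: %d episodes, %d orphan symptom days, %d children (missing rule: %s)\n",
    nrow(x$episodes), nrow(x$orphans), length(x$children), x$missing_rule))
  invisible(x)
}

#' Episode table of a segmentation
#'
#' @param x An `"ari_segmentation"` (or already an episode tibble, returned
#'   as is).
#' @return Tibble of episodes.
#' @export
episode_table <- function(x) {
  if (inherits(x, "ari_segmentation")) x$episodes else tibble::as_tibble(x)
}

#' Episode counts per child and age stratum
#'
#' Each episode is assigned to exactly one stratum by its start day, so the
#' four half-year counts sum to the two-year total for every child.
#'
#' @param x Segmentation object or episode tibble.
#' @param children Optional child universe; children without episodes get
#'   zero counts. Defaults to the segmentation's children.
#' @param include_censored Keep window-censored episodes (default TRUE).
#' @return Tibble: `child_id`, `stratum` (factor: four half-year strata, the
#'   two years, and `0-24mo`), `n_episodes`. Strata overlap by construction
#'   (`0-12mo` = `0-6mo` + `7-12mo`, etc.); within a scheme they are
#'   disjoint.
#' @export
episodes_per_child <- function(x, children = NULL, include_censored = TRUE) {
  ep <- episode_table(x)
  children <- as.character(
    children %||% (if (inherits(x, "ari_segmentation")) x$children
                   else sort(unique(ep$child_id))))
  if (!include_censored) ep <- ep[!ep$censored, , drop = FALSE]

  count_scheme <- function(strat) {
    dplyr::count(
      tibble::tibble(child_id = ep$child_id, stratum = strat),
      .data$child_id, .data$stratum, name = "n_episodes", .drop = FALSE
    )
  }
  counts <- dplyr::bind_rows(
    count_scheme(age_stratum(ep$start_day, "halfyear")),
    count_scheme(age_stratum(ep$start_day, "year")),
    count_scheme(factor(rep("0-24mo", nrow(ep)), levels = "0-24mo"))
  )
  grid <- tidyr::expand_grid(
    child_id = children,
    stratum = factor(STRATUM_LEVELS, levels = STRATUM_LEVELS)
  )
  out <- dplyr::left_join(grid, counts, by = c("child_id", "stratum"))
  out$n_episodes <- dplyr::coalesce(out$n_episodes, 0L)
  out
}

#' Age at first ARI episode
#'
#' Start day of each child's earliest episode; children with no episode are
#' flagged censored (they contribute no age).
#'
#' @inheritParams episodes_per_child
#' @return Tibble: `child_id`, `first_episode_day` (NA if none), `censored`.
#' @export
age_at_first_episode <- function(x, children = NULL) {
  ep <- episode_table(x)
  children <- as.character(
    children %||% (if (inherits(x, "ari_segmentation")) x$children
                   else sort(unique(ep$child_id))))
  firsts <- dplyr::summarise(dplyr::group_by(ep, .data$child_id),
                             first_episode_day = min(.data$start_day),
                             .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(child_id = children), firsts,
                          by = "child_id")
  out$censored <- is.na(out$first_episode_day)
  out
}

#' Summary statistics of episode durations
#'
#' Mean, SD, median and quartiles of episode duration in days, either over
#' all episodes or over per-child mean durations. Quantiles use linear
#' interpolation (`stats::quantile` type 7); the convention is recorded in
#' the output.
#'
#' @inheritParams episodes_per_child
#' @param level `"episode"` (statistics over all episodes) or `"child_mean"`
#'   (over per-child mean durations).
#' @return One-row tibble: `level`, `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `quantile_type`.
#' @export
duration_summary <- function(x, level = c("episode", "child_mean"),
                             include_censored = TRUE) {
  level <- match.arg(level)
  ep <- episode_table(x)
  if (!include_censored) ep <- ep[!ep$censored, , drop = FALSE]
  vals <- if (level == "episode") {
    ep$duration_days
  } else {
    dplyr::summarise(dplyr::group_by(ep, .data$child_id),
                     d = mean(.data$duration_days), .groups = "drop")$d
  }
  qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(level = level, n = length(vals), mean = mean(vals),
                 sd = sd(vals), median = qs[2], q1 = qs[1], q3 = qs[3],
                 quantile_type = 7L)
}

#' Summary grid of per-child episode counts by age stratum
#'
#' Min / quartiles / mean / max of per-child episode counts for the four
#' half-year strata, the two years of life, and overall.
#'
#' @inheritParams episodes_per_child
#' @return Tibble with a `stat` column (`min`, `q1`, `median`, `mean`, `q3`,
#'   `max`) and one column per stratum.
#' @export
episode_count_grid <- function(x, children = NULL, include_censored = TRUE) {
  counts <- episodes_per_child(x, children, include_censored)
  summary_grid(counts, value = "n_episodes", by = "stratum")
}

# Shared Min/Q1/Median/Mean/Q3/Max grid builder (Tables 2 and 3 layout).
summary_grid <- function(df, value, by) {
  long <- dplyr::summarise(
    dplyr::group_by(df, .data[[by]]),
    min = min(.data[[value]]),
    q1 = quantile(.data[[value]], 0.25, names = FALSE, type = 7),
    median = quantile(.data[[value]], 0.5, names = FALSE, type = 7),
    mean = mean(.data[[value]]),
    q3 = quantile(.data[[value]], 0.75, names = FALSE, type = 7),
    max = max(.data[[value]]),
    .groups = "drop"
  )
  out <- tidyr::pivot_longer(long, -dplyr::all_of(by), names_to = "stat")
  out <- tidyr::pivot_wider(out, names_from = dplyr::all_of(by),
                            values_from = "value")
  out$stat <- factor(out$stat, levels = c("min", "q1", "median", "mean", "q3", "max"))
  dplyr::arrange(out, .data$stat)
}
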
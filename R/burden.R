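# Symptom-day burden, prevalence curves and stratum mean differences.

#' Per-child and cohort symptom-day burden
#'
#' A child-day is symptomatic iff at least one symptom flag is set (any day
#' class except FREE/MISSING), so isolated single-B days outside episodes
#' count toward burden. Per-symptom totals count each day the flag is set;
#' `cough` combines wet and dry cough ("cough in various forms"). Wet and
#' dry cough on one day is still one cough day.
#'
#' @param diary Validated diary tibble (included children only).
#' @param window An [observation_window()].
#' @return A list with class `"cohort_burden"`:
#'   \describe{
#'     \item{per_child}{tibble of per-child totals: symptom days overall and
#'       per half-year stratum, plus days per specific symptom.}
#'     \item{cohort}{one-row tibble: observed child-days, symptomatic days,
#'       symptomatic fraction.}
#'     \item{table}{Min/Q1/Median/Mean/Q3/Max grid over children: the four
#'       strata, the overall total, and the specific symptoms.}
#'   }
#' @export
symptom_day_summary <- function(diary, window = observation_window()) {
  in_win <- diary[diary$day_of_life >= window$start_day &
                    diary$day_of_life <= window$end_day, , drop = FALSE]
  sym_mat <- as.matrix(in_win[, ARI_SYMPTOMS, drop = FALSE]) > 0
  symptomatic <- rowSums(sym_mat) > 0

  per_day <- tibble::tibble(
    child_id = in_win$child_id,
    stratum = age_stratum(in_win$day_of_life, "halfyear"),
    symptomatic = symptomatic,
    cough = in_win$wet_cough > 0 | in_win$dry_cough > 0
  )
  for (s in ARI_SYMPTOMS) per_day[[s]] <- in_win[[s]] > 0

  by_stratum <- dplyr::summarise(
    dplyr::group_by(per_day, .data$child_id, .data$stratum, .drop = FALSE),
    days = sum(.data$symptomatic), .groups = "drop"
  )
  by_stratum <- tidyr::pivot_wider(by_stratum, names_from = "stratum",
                                   values_from = "days", values_fill = 0L)
  totals <- dplyr::summarise(
    dplyr::group_by(per_day, .data$child_id),
    overall = sum(.data$symptomatic),
    dplyr::across(dplyr::all_of(c("cough", ARI_SYMPTOMS)), sum),
    .groups = "drop"
  )
  per_child <- dplyr::left_join(by_stratum, totals, by = "child_id")

  cohort <- tibble::tibble(
    child_days = nrow(in_win),
    symptomatic_days = sum(symptomatic),
    fraction_symptomatic = sum(symptomatic) / nrow(in_win)
  )

  long <- tidyr::pivot_longer(per_child, -"child_id",
                              names_to = "measure", values_to = "days")
  long$measure <- factor(long$measure, levels = setdiff(names(per_child), "child_id"))
  grid <- summary_grid(long, value = "days", by = "measure")

  structure(list(per_child = per_child, cohort = cohort, table = grid),
            class = "cohort_burden")
}

#' @export
print.cohort_burden <- function(x, ...) {
  cat(sprintf(
    "Cohort burden: %d child-days, %d symptomatic (%.1f%%), %d children\n",
    x$cohort$child_days, x$cohort$symptomatic_days,
    100 * x$cohort$fraction_symptomatic, nrow(x$per_child)))
  invisible(x)
}

#' Empirical cumulative distribution of per-child symptom-day totals
#'
#' One ECDF per measure (overall symptom days and each specific symptom):
#' the fraction of children with at most that many days. Curves are monotone
#' non-decreasing and reach 1.
#'
#' @param burden A `"cohort_burden"` (or its `per_child` tibble).
#' @param measures Which columns to include; defaults to all measures.
#' @return Tibble: `measure`, `days`, `cdf`.
#' @export
percentile_curves <- function(burden, measures = NULL) {
  per_child <- if (inherits(burden, "cohort_burden")) burden$per_child else burden
  measures <- measures %||% setdiff(names(per_child), "child_id")
  long <- tidyr::pivot_longer(per_child[, c("child_id", measures)], -"child_id",
                              names_to = "measure", values_to = "days")
  out <- dplyr::reframe(
    dplyr::group_by(long, .data$measure),
    days = sort(unique(.data$days)),
    cdf = vapply(sort(unique(.data$days)),
                 function(v) mean(.data$days <= v), numeric(1))
  )
  tibble::as_tibble(out)
}

# In-episode indicator per observed child-day.
in_episode_days <- function(diary, segmentation) {
  ep <- episode_table(segmentation)
  if (!nrow(ep)) {
    return(tibble::tibble(child_id = character(), day_of_life = integer()))
  }
  days <- purrr::map2(ep$start_day, ep$last_symptom_day, seq.int)
  tidyr::unnest(tibble::tibble(child_id = ep$child_id, day_of_life = days),
                "day_of_life")
}

#' Daily ARI prevalence over the first two years of life
#'
#' For each day of life, the proportion of children inside an ARI episode.
#' The default denominator is observed (non-missing) child-days for that
#' day; `denominator = "cohort"` uses all children in the segmentation.
#'
#' @param diary Validated diary tibble (included children only).
#' @param segmentation An `"ari_segmentation"` for the same children.
#' @param denominator `"observed"` or `"cohort"`.
#' @return Tibble with class `"ari_prevalence"`: `axis` (`day_of_life`),
#'   `value`, `numerator`, `denominator`, `proportion`.
#' @export
prevalence_by_day <- function(diary, segmentation,
                              denominator = c("observed", "cohort")) {
  denominator <- match.arg(denominator)
  window <- segmentation$window
  ep_days <- in_episode_days(diary, segmentation)
  ep_days$in_episode <- TRUE
  obs <- dplyr::left_join(
    diary[diary$day_of_life >= window$start_day &
            diary$day_of_life <= window$end_day,
          c("child_id", "day_of_life")],
    ep_days, by = c("child_id", "day_of_life"))
  obs$in_episode <- dplyr::coalesce(obs$in_episode, FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(obs, .data$day_of_life),
    numerator = sum(.data$in_episode),
    denominator = if (denominator == "observed") dplyr::n()
                  else length(segmentation$children),
    .groups = "drop")
  out <- tibble::tibble(axis = "day_of_life", value = out$day_of_life,
                        numerator = out$numerator, denominator = out$denominator,
                        proportion = out$numerator / out$denominator)
  class(out) <- c("ari_prevalence", class(out))
  out
}

#' Monthly (seasonal) ARI prevalence
#'
#' Proportion of observed child-days inside an ARI episode, by calendar
#' month of the diary date. Winter peaks indicate the expected northern-
#' hemisphere seasonality of respiratory infections.
#'
#' @inheritParams prevalence_by_day
#' @return Tibble with class `"ari_prevalence"`: `axis` (`month`), `value`
#'   (1--12), `month` (abbreviated name), `numerator`, `denominator`,
#'   `proportion`.
#' @export
prevalence_by_month <- function(diary, segmentation,
                                denominator = c("observed", "cohort")) {
  denominator <- match.arg(denominator)
  window <- segmentation$window
  ep_days <- in_episode_days(diary, segmentation)
  ep_days$in_episode <- TRUE
  obs <- diary[diary$day_of_life >= window$start_day &
                 diary$day_of_life <= window$end_day,
               c("child_id", "day_of_life", "date")]
  obs <- dplyr::left_join(obs, ep_days, by = c("child_id", "day_of_life"))
  obs$in_episode <- dplyr::coalesce(obs$in_episode, FALSE)
  obs$month <- as.integer(format(obs$date, "%m"))
  out <- dplyr::summarise(
    dplyr::group_by(obs, .data$month),
    numerator = sum(.data$in_episode),
    denominator = dplyr::n(),
    .groups = "drop")
  if (denominator == "cohort") {
    # every child contributes ~2 observations of each calendar month
    out$denominator <- length(segmentation$children) * 2L *
      c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[out$month]
  }
  out <- tibble::tibble(axis = "month", value = out$month,
                        month = month.abb[out$month],
                        numerator = out$numerator, denominator = out$denominator,
                        proportion = out$numerator / out$denominator)
  class(out) <- c("ari_prevalence", class(out))
  out
}

# Default cohort-description strata: reference level per covariate
# (female, full-term, vaginal, 0 siblings, 4-6 mo breastfeeding, no daycare).
DESCRIPTION_REFERENCES <- c(
  sex = "female", birth_term = "full_term", birth_mode = "vaginal",
  older_siblings = "0", breastfeeding = "4-6mo",
  daycare_entry = "none_by_24mo"
)

#' Welch mean differences of episode counts across covariate strata
#'
#' For each level of each covariate, the mean two-year episode count, the
#' difference to the covariate's reference level, and its 95% Welch
#' (unequal-variance, two-sided) confidence interval.
#'
#' @param counts Tibble `child_id`, `n_episodes` (e.g.
#'   [episodes_per_child()] filtered to the `0-24mo` stratum).
#' @param covariates Covariate table restricted to the same children.
#' @param variables Named character vector mapping covariate column ->
#'   reference level; defaults to the standard cohort-description set.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `covariate`, `level`, `n`, `mean`, `is_reference`,
#'   `difference`, `conf_low`, `conf_high`.
#' @export
strata_mean_difference <- function(counts, covariates,
                                   variables = DESCRIPTION_REFERENCES,
                                   conf_level = 0.95) {
  df <- dplyr::inner_join(counts, covariates, by = "child_id")
  rows <- purrr::imap(variables, function(ref, var) {
    vals <- as.character(df[[var]])
    keep <- !is.na(vals)
    levels_here <- if (is.factor(df[[var]])) levels(df[[var]]) else sort(unique(vals[keep]))
    if (!ref %in% levels_here) {
      abort(sprintf("reference level '%s' not a level of '%s'", ref, var))
    }
    ref_counts <- df$n_episodes[keep & vals == ref]
    purrr::map_dfr(levels_here, function(lv) {
      grp <- df$n_episodes[keep & vals == lv]
      if (!length(grp)) return(NULL)
      if (lv == ref) {
        tibble::tibble(covariate = var, level = lv, n = length(grp),
                       mean = mean(grp), is_reference = TRUE,
                       difference = NA_real_, conf_low = NA_real_,
                       conf_high = NA_real_)
      } else {
        tt <- t.test(grp, ref_counts, conf.level = conf_level)
        tibble::tibble(covariate = var, level = lv, n = length(grp),
                       mean = mean(grp), is_reference = FALSE,
                       difference = mean(grp) - mean(ref_counts),
                       conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
      }
    })
  })
  dplyr::bind_rows(rows)
}
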
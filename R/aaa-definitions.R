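# Case-definition vocabulary.
#
# A-symptoms can start an episode on their own; two distinct B-symptoms on
# one day can also start one. Doctor-diagnosed pneumonia / otitis media count
# as A-symptoms. Wet and dry cough are distinct codes: the A/B split depends
# on cough type.

ARI_A_SYMPTOMS <- c("fever", "wheezing", "wet_cough")

ARI_B_SYMPTOMS <- c(
  "dry_cough", "chills", "sore_throat", "runny_or_blocked_nose",
  "increased_need_to_sleep", "loss_of_appetite", "increased_attachment"
)

ARI_SYMPTOMS <- c(
  "fever", "wheezing", "wet_cough", "dry_cough", "chills", "sore_throat",
  "runny_or_blocked_nose", "increased_need_to_sleep", "loss_of_appetite",
  "increased_attachment"
)

ARI_DX_FLAGS <- c("dx_pneumonia", "dx_otitis_media")

DAY_CLASSES <- c("A_DAY", "B_PAIR_DAY", "SINGLE_B_DAY", "FREE", "MISSING")

# Canonical covariate levels (first level = model reference).
COVARIATE_LEVELS <- list(
  sex            = c("male", "female"),
  birth_term     = c("full_term", "early_term"),
  birth_mode     = c("vaginal", "c_section"),
  older_siblings = c("0", "1", "2+"),
  breastfeeding  = c("4-6mo", "none", "1-3mo", "7-13mo"),
  daycare_entry  = c("none_by_24mo", "0-12mo", "13-26mo")
)

#' Symptom codes of the ARI case definition
#'
#' The ten diary symptoms, split into A-symptoms (fever, wheezing, wet cough
#' -- any one can start an episode, as can a doctor-diagnosed pneumonia or
#' otitis media) and B-symptoms (dry cough, chills, sore throat, runny or
#' blocked nose, increased need to sleep, loss of appetite, increased
#' attachment -- two distinct ones on the same day can start an episode).
#'
#' @param type `"all"`, `"A"`, or `"B"`.
#' @return Character vector of symptom column names.
#' @export
#' @examples
#' symptom_codes("A")
symptom_codes <- function(type = c("all", "A", "B")) {
  switch(match.arg(type), all = ARI_SYMPTOMS, A = ARI_A_SYMPTOMS, B = ARI_B_SYMPTOMS)
}

#' Observation window for the two-year diary analysis
#'
#' Days of life 0--729 inclusive (730 days, "first two years of life") with a
#' diary-completeness inclusion threshold of 98%.
#'
#' @param start_day,end_day First and last day of life covered (inclusive).
#' @param completeness_threshold Minimum fraction of window days with a diary
#'   entry for a child to be included.
#' @return A list with class `"observation_window"`: `start_day`, `end_day`,
#'   `n_days`, `completeness_threshold`.
#' @export
#' @examples
#' observation_window()
observation_window <- function(start_day = 0L, end_day = 729L,
                               completeness_threshold = 0.98) {
  start_day <- as.integer(start_day)
  end_day <- as.integer(end_day)
  stopifnot(end_day >= start_day,
            completeness_threshold >= 0, completeness_threshold <= 1)
  structure(
    list(start_day = start_day, end_day = end_day,
         n_days = end_day - start_day + 1L,
         completeness_threshold = completeness_threshold),
    class = "observation_window"
  )
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("Observation window: days %d-%d (%d days), completeness threshold %.2f\n",
              x$start_day, x$end_day, x$n_days, x$completeness_threshold))
  invisible(x)
}

# Age-stratum day boundaries: four equal 6-month bins over the 730-day window
# (0-6 mo = d0-182, 7-12 = d183-365, 13-18 = d366-547, 19-24 = d548-729),
# plus year and overall strata built from the same cuts.
STRATA_HALFYEAR <- tibble::tibble(
  stratum = c("0-6mo", "7-12mo", "13-18mo", "19-24mo"),
  from = c(0L, 183L, 366L, 548L),
  to = c(182L, 365L, 547L, 729L)
)

STRATA_YEAR <- tibble::tibble(
  stratum = c("0-12mo", "13-24mo"),
  from = c(0L, 366L),
  to = c(365L, 729L)
)

STRATUM_LEVELS <- c("0-6mo", "7-12mo", "13-18mo", "19-24mo",
                    "0-12mo", "13-24mo", "0-24mo")

#' Assign days of life to age strata
#'
#' @param day_of_life Integer vector of days since birth (0 = birth date).
#' @param scheme `"halfyear"` (four 6-month strata) or `"year"` (two 1-year
#'   strata).
#' @return Factor of stratum labels.
#' @export
#' @examples
#' age_stratum(c(0, 182, 183, 365, 366, 729))
age_stratum <- function(day_of_life, scheme = c("halfyear", "year")) {
  scheme <- match.arg(scheme)
  cuts <- if (scheme == "halfyear") STRATA_HALFYEAR else STRATA_YEAR
  idx <- findInterval(day_of_life, cuts$from)
  idx[day_of_life < cuts$from[1] | day_of_life > cuts$to[nrow(cuts)]] <- NA_integer_
  factor(cuts$stratum[idx], levels = cuts$stratum)
}
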
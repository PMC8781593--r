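# Synthetic cohort generator: covariates, two-year daily diaries, and the
# latent ground-truth episode table.
#
# Episodes arise from a discrete-time daily Bernoulli onset hazard
#   P(onset on day t) = h0 * a(age_t) * s(month_t) * exp(beta' x),
# evaluated only outside latent episodes and their 3-day refractory tails.
# The refractory tail guarantees >= 3 symptom-free days after every episode,
# so with no missingness and guarded orphan days the case-definition
# segmentation recovers the latent truth exactly.

#' Simulation configuration
#'
#' Defaults emulate the study cohort: covariate margins from the published
#' cohort description; covariate effects on the onset hazard equal to the
#' published adjusted rate ratios; lognormal episode durations with mean 11
#' and SD 5.8 days (median 9.7), truncated at one day; an age ramp rising
#' from 6.5% of the adult-of-cohort hazard at birth to 100% by day 182
#' (placing the median first episode near day 91); a winter-peaked seasonal
#' sinusoid with peak/trough ratio 2; and a baseline hazard calibrated so
#' the mean two-year episode count is close to 13.7. Missingness defaults to
#' 1% of days (the emulated cohort is the >= 98%-completeness subsample).
#'
#' @param n_children Number of children.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param h0 Baseline daily onset hazard.
#' @param age_ramp_start Hazard multiplier at birth (ramps linearly to 1).
#' @param age_ramp_full_day Day of life at which the ramp reaches 1.
#' @param season_amplitude Amplitude of the seasonal sinusoid
#'   `s(m) = 1 + amplitude * cos(2 * pi * (m - peak) / 12)`.
#' @param season_peak_month Month (fractional) of the seasonal peak.
#' @param beta Named list of per-covariate named numeric vectors: log rate
#'   effects of non-reference levels on the onset hazard.
#' @param p_male,p_siblings,p_breastfeeding,p_daycare,p_c_section,
#'   p_early_term,p_pets Covariate margins.
#' @param birth_date_start First possible birth date; births are uniform
#'   over the following 365 days so age and season effects are separable.
#' @param duration_meanlog,duration_sdlog Lognormal episode-duration
#'   parameters (days; rounded, truncated at 1).
#' @param p_a_trigger Probability that an episode's first day carries an
#'   A-symptom (otherwise two distinct B-symptoms).
#' @param a_trigger_weights Sampling weights over the three A-symptoms for
#'   the day-1 trigger.
#' @param emission Named per-symptom daily emission probabilities inside an
#'   episode (runny/blocked nose highest); a day drawing no symptom is
#'   assigned runny/blocked nose so every episode day is symptomatic.
#' @param dx_rate Daily probability of a doctor-diagnosis flag on episode
#'   days.
#' @param orphan_rate Daily rate of isolated single-B-symptom days outside
#'   episodes (kept >= 3 days clear of any episode so the latent truth stays
#'   unambiguous).
#' @param missing_rate Daily probability that a diary entry is missing
#'   (<= 0.02).
#' @return A list with class `"ari_sim_config"`.
#' @export
sim_config <- function(n_children = 288L,
                       seed = 1L,
                       h0 = 0.0234,
                       age_ramp_start = 0.065,
                       age_ramp_full_day = 182L,
                       season_amplitude = 1 / 3,
                       season_peak_month = 1.5,
                       beta = list(
                         breastfeeding = c("none" = log(0.90),
                                           "1-3mo" = log(0.78),
                                           "7-13mo" = log(1.00)),
                         daycare_entry = c("0-12mo" = log(1.27),
                                           "13-26mo" = log(1.27)),
                         birth_mode = c("c_section" = log(0.99)),
                         birth_term = c("early_term" = log(1.10)),
                         sex = c("female" = log(1.01)),
                         older_siblings = c("1" = log(1.08),
                                            "2+" = log(1.17))
                       ),
                       p_male = 0.48,
                       p_siblings = c("0" = 0.682, "1" = 0.255, "2+" = 0.063),
                       p_breastfeeding = c("4-6mo" = 0.618, "none" = 0.056,
                                           "1-3mo" = 0.094, "7-13mo" = 0.232),
                       p_daycare = c("none_by_24mo" = 0.156, "0-12mo" = 0.340,
                                     "13-26mo" = 0.504),
                       p_c_section = 0.23,
                       p_early_term = 0.076,
                       p_pets = 0.278,
                       birth_date_start = as.Date("2015-01-01"),
                       duration_meanlog = 2.2752,
                       duration_sdlog = 0.4953,
                       p_a_trigger = 0.7,
                       a_trigger_weights = c(fever = 0.35, wheezing = 0.15,
                                             wet_cough = 0.50),
                       emission = c(fever = 0.09, wheezing = 0.08,
                                    wet_cough = 0.25, dry_cough = 0.25,
                                    chills = 0.003, sore_throat = 0.02,
                                    runny_or_blocked_nose = 0.80,
                                    increased_need_to_sleep = 0.15,
                                    loss_of_appetite = 0.15,
                                    increased_attachment = 0.27),
                       dx_rate = 0.002,
                       orphan_rate = 0.005,
                       missing_rate = 0.01) {
  stopifnot(
    n_children >= 1, h0 >= 0, missing_rate >= 0, missing_rate <= 0.02 + 1e-12,
    orphan_rate >= 0, orphan_rate <= 1, p_a_trigger >= 0, p_a_trigger <= 1,
    all(emission >= 0 & emission <= 1),
    abs(sum(p_siblings) - 1) < 1e-6, abs(sum(p_breastfeeding) - 1) < 1e-6,
    abs(sum(p_daycare) - 1) < 1e-6
  )
  if (!setequal(names(emission), ARI_SYMPTOMS)) {
    abort("emission probabilities must name exactly the ten symptom codes")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "ari_sim_config")
}

#' @export
print.ari_sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d children, seed %d, h0 = %.4f, missing rate %.3f\n",
    x$n_children, x$seed, x$h0, x$missing_rate))
  invisible(x)
}

# Age multiplier: linear ramp from age_ramp_start at day 0 to 1 at
# age_ramp_full_day, constant thereafter.
age_multiplier <- function(day_of_life, config) {
  r0 <- config$age_ramp_start
  pmin(1, r0 + (1 - r0) * day_of_life / config$age_ramp_full_day)
}

# Seasonal multiplier (mean ~ 1 over the year), winter peak.
season_multiplier <- function(month, config) {
  1 + config$season_amplitude *
    cos(2 * pi * (month - config$season_peak_month) / 12)
}

# exp(beta' x) per child.
covariate_multiplier <- function(covariates, config) {
  log_mult <- rep(0, nrow(covariates))
  for (var in names(config$beta)) {
    b <- config$beta[[var]]
    vals <- as.character(covariates[[var]])
    hit <- match(vals, names(b))
    log_mult <- log_mult + ifelse(is.na(hit), 0, b[hit])
  }
  exp(log_mult)
}

#' Simulate a covariate table
#'
#' Independent categorical draws per child from the configured margins;
#' birth dates uniform over one calendar year; birth weight normal
#' (3400, 488) g. Fully reproducible from `config$seed`.
#'
#' @param config An [sim_config()].
#' @return Covariate tibble in the [read_covariates()] layout.
#' @export
simulate_covariates <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_children
  draw <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  cov <- tibble::tibble(
    child_id = sprintf("sim%05d", seq_len(n)),
    birth_date = config$birth_date_start + sample.int(365L, n, replace = TRUE) - 1L,
    sex = factor(ifelse(runif(n) < config$p_male, "male", "female"),
                 levels = COVARIATE_LEVELS$sex),
    birth_term = factor(ifelse(runif(n) < config$p_early_term,
                               "early_term", "full_term"),
                        levels = COVARIATE_LEVELS$birth_term),
    birth_mode = factor(ifelse(runif(n) < config$p_c_section,
                               "c_section", "vaginal"),
                        levels = COVARIATE_LEVELS$birth_mode),
    birth_weight_g = as.integer(round(rnorm(n, 3400, 488))),
    older_siblings = draw(config$p_siblings),
    breastfeeding = draw(config$p_breastfeeding),
    daycare_entry = draw(config$p_daycare),
    pets = runif(n) < config$p_pets
  )
  cov$older_siblings <- factor(cov$older_siblings,
                               levels = COVARIATE_LEVELS$older_siblings)
  cov$breastfeeding <- factor(cov$breastfeeding,
                              levels = COVARIATE_LEVELS$breastfeeding)
  cov$daycare_entry <- factor(cov$daycare_entry,
                              levels = COVARIATE_LEVELS$daycare_entry)
  cov
}

# simulate one child's latent episodes and symptom matrix
simulate_child <- function(p_onset, config) {
  n_days <- length(p_onset)
  sym <- matrix(0L, n_days, length(ARI_SYMPTOMS),
                dimnames = list(NULL, ARI_SYMPTOMS))
  dx <- matrix(0L, n_days, 2L, dimnames = list(NULL, ARI_DX_FLAGS))
  em <- config$emission

  onset <- integer(); last <- integer(); trig <- character()
  truncated <- 0L

  u <- runif(n_days)
  t <- 1L
  while (t <= n_days) {
    hit <- which(u[t:n_days] < p_onset[t:n_days])
    if (!length(hit)) break
    s <- t + hit[1L] - 1L
    dur <- max(1L, as.integer(round(rlnorm(1, config$duration_meanlog,
                                           config$duration_sdlog))))
    e_raw <- s + dur - 1L
    e <- min(e_raw, n_days)
    if (e_raw > n_days) truncated <- truncated + 1L

    a_trig <- runif(1) < config$p_a_trigger
    if (a_trig) {
      first <- sample(names(config$a_trigger_weights), 1L,
                      prob = config$a_trigger_weights)
      sym[s, first] <- 1L
      extra <- ARI_SYMPTOMS[runif(length(ARI_SYMPTOMS)) < em[ARI_SYMPTOMS]]
      sym[s, extra] <- 1L
      trig <- c(trig, "A_symptom")
    } else {
      wb <- em[ARI_B_SYMPTOMS] / sum(em[ARI_B_SYMPTOMS])
      pair <- sample(ARI_B_SYMPTOMS, 2L, prob = wb)
      sym[s, pair] <- 1L
      extra <- ARI_B_SYMPTOMS[runif(length(ARI_B_SYMPTOMS)) < em[ARI_B_SYMPTOMS]]
      sym[s, extra] <- 1L
      trig <- c(trig, "B_pair")
    }
    if (e > s) {
      rest <- (s + 1L):e
      draws <- matrix(runif(length(rest) * length(ARI_SYMPTOMS)),
                      nrow = length(rest))
      hits <- sweep(draws, 2L, em[ARI_SYMPTOMS], "<")
      none <- rowSums(hits) == 0
      hits[none, match("runny_or_blocked_nose", ARI_SYMPTOMS)] <- TRUE
      sym[rest, ] <- sym[rest, ] | hits
    }
    # diagnosis flags: only on days already carrying an A-symptom, so a
    # B-pair-triggered start day stays a pure B-pair
    ep_days <- s:e
    a_days <- ep_days[rowSums(sym[ep_days, ARI_A_SYMPTOMS, drop = FALSE]) > 0]
    if (length(a_days)) {
      dx[a_days, ] <- matrix(
        as.integer(runif(length(a_days) * 2L) < config$dx_rate),
        ncol = 2L)
    }

    onset <- c(onset, s); last <- c(last, e)
    t <- e + 4L                      # 3 guaranteed free days, then at risk
  }

  # orphan single-B days: outside episodes, >= 3 clear days before a start
  # and >= 4 after an end (so the 3-day closure window stays symptom-free)
  if (config$orphan_rate > 0) {
    forbidden <- rep(FALSE, n_days)
    for (k in seq_along(onset)) {
      lo <- max(1L, onset[k] - 3L); hi <- min(n_days, last[k] + 4L)
      forbidden[lo:hi] <- TRUE
    }
    cand <- which(!forbidden)
    orphan <- cand[runif(length(cand)) < config$orphan_rate]
    if (length(orphan)) {
      wb <- em[ARI_B_SYMPTOMS] / sum(em[ARI_B_SYMPTOMS])
      sym[cbind(orphan,
                match(sample(ARI_B_SYMPTOMS, length(orphan), replace = TRUE,
                             prob = wb), ARI_SYMPTOMS))] <- 1L
    }
  }

  storage.mode(sym) <- "integer"
  list(sym = sym, dx = dx, onset = onset, last = last, trig = trig,
       truncated = truncated)
}

#' Simulate daily diaries and the latent episode truth
#'
#' For each child and each at-risk day, an episode begins with probability
#' `h0 * a(age) * s(month) * exp(beta' x)`; its duration is lognormal; its
#' first day is guaranteed to satisfy the episode start rule (an A-symptom
#' with probability `p_a_trigger`, otherwise two distinct B-symptoms) and
#' every later episode day carries at least one symptom. Three symptom-free
#' days are guaranteed after each episode. Isolated single-B-symptom days
#' are sprinkled outside episodes (kept clear of episode margins), then
#' missing days are deleted. The latent episode table is exported as ground
#' truth.
#'
#' @param covariates Covariate table from [simulate_covariates()].
#' @param config The same [sim_config()].
#' @return A list: `diary` (validated-diary-shaped tibble of present days),
#'   `truth` (tibble `child_id`, `start_day`, `last_symptom_day`,
#'   `duration_days`, `trigger`, `censored`, `n_symptom_days`).
#' @export
simulate_diaries <- function(covariates, config = sim_config()) {
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  n_days <- 730L
  mult <- covariate_multiplier(covariates, config)
  age_m <- age_multiplier(0:(n_days - 1L), config)

  sym_list <- vector("list", nrow(covariates))
  dx_list <- vector("list", nrow(covariates))
  present_list <- vector("list", nrow(covariates))
  truth_list <- vector("list", nrow(covariates))
  n_truncated <- 0L

  for (i in seq_len(nrow(covariates))) {
    dates <- covariates$birth_date[i] + 0:(n_days - 1L)
    month <- as.POSIXlt(dates)$mon + 1L
    p <- pmin(0.95, config$h0 * age_m * season_multiplier(month, config) * mult[i])
    ch <- simulate_child(p, config)
    n_truncated <- n_truncated + ch$truncated

    present <- runif(n_days) >= config$missing_rate
    present_list[[i]] <- which(present)
    sym_list[[i]] <- ch$sym[present, , drop = FALSE]
    dx_list[[i]] <- ch$dx[present, , drop = FALSE]

    truth_list[[i]] <- tibble::tibble(
      child_id = covariates$child_id[i],
      start_day = ch$onset - 1L,
      last_symptom_day = ch$last - 1L,
      duration_days = ch$last - ch$onset + 1L,
      trigger = ch$trig,
      censored = ch$last - 1L >= n_days - 3L,
      n_symptom_days = ch$last - ch$onset + 1L
    )
  }
  if (n_truncated > 0) {
    inform(sprintf("%d episode duration(s) truncated at the window end",
                   n_truncated))
  }

  n_present <- lengths(present_list)
  child_id <- rep(covariates$child_id, n_present)
  day_of_life <- unlist(present_list) - 1L
  date <- rep(covariates$birth_date, n_present) + day_of_life
  diary <- tibble::as_tibble(do.call(rbind, sym_list))
  dxt <- tibble::as_tibble(do.call(rbind, dx_list))
  diary <- dplyr::bind_cols(
    tibble::tibble(child_id = child_id, date = date, day_of_life = day_of_life),
    diary, dxt)
  diary$entry_present <- TRUE

  list(diary = diary,
       truth = dplyr::bind_rows(truth_list))
}

#' Simulate a full cohort (covariates + diaries + truth)
#'
#' @param config An [sim_config()].
#' @return A list: `covariates`, `diary`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  covariates <- simulate_covariates(config)
  sim <- simulate_diaries(covariates, config)
  list(covariates = covariates, diary = sim$diary, truth = sim$truth,
       config = config)
}
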
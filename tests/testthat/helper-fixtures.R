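# Fixture builders: tiny diaries specified day-by-day as symptom sets.

ALL_SYMPTOMS <- symptom_codes()
A_SYMPTOMS <- symptom_codes("A")
B_SYMPTOMS <- symptom_codes("B")

# days: named list, names = day_of_life, values = character vectors of
# symptom codes and/or "dx_pneumonia"/"dx_otitis_media". An empty vector is
# a recorded symptom-free day; a day absent from the list is missing.
make_diary <- function(days, child_id = "c1",
                       birth_date = as.Date("2015-01-01")) {
  dol <- as.integer(names(days))
  out <- tibble::tibble(
    child_id = child_id,
    date = birth_date + dol,
    day_of_life = dol
  )
  for (col in c(ALL_SYMPTOMS, "dx_pneumonia", "dx_otitis_media")) {
    out[[col]] <- vapply(days, function(d) as.integer(col %in% d), integer(1))
  }
  out$entry_present <- TRUE
  out
}

# a fully observed diary over 0..(n_days-1); `symptomatic` is a list
# day -> symptom set overriding the default free day
full_diary <- function(n_days = 730, symptomatic = list(), ...) {
  days <- stats::setNames(rep(list(character()), n_days),
                          as.character(seq_len(n_days) - 1L))
  for (d in names(symptomatic)) days[[d]] <- symptomatic[[d]]
  make_diary(days, ...)
}

make_covariates <- function(child_id = "c1",
                            birth_date = as.Date("2015-01-01")) {
  tibble::tibble(
    child_id = child_id,
    birth_date = birth_date,
    sex = factor("male", levels = c("male", "female")),
    birth_term = factor("full_term", levels = c("full_term", "early_term")),
    birth_mode = factor("vaginal", levels = c("vaginal", "c_section")),
    birth_weight_g = 3400L,
    older_siblings = factor("0", levels = c("0", "1", "2+")),
    breastfeeding = factor("4-6mo", levels = c("4-6mo", "none", "1-3mo", "7-13mo")),
    daycare_entry = factor("none_by_24mo",
                           levels = c("none_by_24mo", "0-12mo", "13-26mo")),
    pets = FALSE
  )
}

# random short diary: per present day, independent rare symptom flags
random_diary <- function(n_days = 60, p_symptom = 0.06, p_missing = 0.1,
                         p_dx = 0.005, child_id = "r1",
                         birth_date = as.Date("2015-01-01")) {
  present <- which(runif(n_days) >= p_missing)
  days <- lapply(present, function(d) {
    s <- ALL_SYMPTOMS[runif(length(ALL_SYMPTOMS)) < p_symptom]
    dx <- c("dx_pneumonia", "dx_otitis_media")[runif(2) < p_dx]
    c(s, dx)
  })
  names(days) <- as.character(present - 1L)
  make_diary(days, child_id = child_id, birth_date = birth_date)
}
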
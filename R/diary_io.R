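# Reading, validating and filtering symptom-diary and covariate tables.
#
# Diary CSV interface: one row per recorded child-day, columns
#   child_id,date,<ten symptom columns>,dx_pneumonia,dx_otitis_media
# symptom columns coded 0/1 or 0..3 (0 = absent; 1-3 = present with ordinal
# severity, carried but unused analytically). A missing diary day is an
# absent row, distinct from a recorded symptom-free day (all zeros).

DIARY_COLUMNS <- c("child_id", "date", ARI_SYMPTOMS, ARI_DX_FLAGS)

COVARIATE_COLUMNS <- c("child_id", "birth_date", "sex", "birth_term",
                       "birth_mode", "birth_weight_g", "older_siblings",
                       "breastfeeding", "daycare_entry", "pets")

#' Read and validate a covariate (questionnaire) table
#'
#' One row per child: birth date, sex, birth term (early term = before
#' 38 weeks + 4 days), birth mode, birth weight, older siblings, duration of
#' exclusive breastfeeding, age at daycare entry, pets. Categorical levels
#' must match the canonical level sets; `NA` marks a missing questionnaire
#' answer (complete-case handling happens at modelling time).
#'
#' @param path CSV file path.
#' @return A tibble, one row per child, with categorical columns as factors
#'   (reference level first).
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("child_id", "birth_date"), names(cov))
  if (length(missing_cols)) {
    abort(paste0("covariates file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cov$child_id <- as.character(cov$child_id)
  cov$birth_date <- as.Date(cov$birth_date)
  if (anyDuplicated(cov$child_id)) {
    abort(paste0("duplicate child_id in covariates: ",
                 paste(unique(cov$child_id[duplicated(cov$child_id)]), collapse = ", ")))
  }
  validate_covariates(cov)
}

#' Validate covariate levels and coerce to factors
#'
#' @param cov Covariate data frame (see [read_covariates()]).
#' @return The validated tibble with canonical factor levels.
#' @export
validate_covariates <- function(cov) {
  cov <- tibble::as_tibble(cov)
  for (var in names(COVARIATE_LEVELS)) {
    if (!var %in% names(cov)) next
    vals <- as.character(cov[[var]])
    bad <- setdiff(unique(vals[!is.na(vals)]), COVARIATE_LEVELS[[var]])
    if (length(bad)) {
      abort(sprintf("unknown level(s) in covariate '%s': %s (expected %s)",
                    var, paste(bad, collapse = ", "),
                    paste(COVARIATE_LEVELS[[var]], collapse = ", ")))
    }
    cov[[var]] <- factor(vals, levels = COVARIATE_LEVELS[[var]])
  }
  if ("pets" %in% names(cov)) cov$pets <- as.logical(cov$pets)
  cov
}

#' Read and validate a daily symptom diary
#'
#' Reads the diary CSV, checks the schema (unknown columns are an error
#' naming the column), joins each child's birth date to derive the day of
#' life, drops rows outside the observation window (with a message), and
#' errors on duplicate (child_id, date) rows or on children absent from the
#' covariate table.
#'
#' @param path CSV file path.
#' @param covariates Covariate table from [read_covariates()] (supplies birth
#'   dates).
#' @param window An [observation_window()].
#' @return A tibble of validated diary days: `child_id`, `date`,
#'   `day_of_life`, the ten symptom columns (integer 0--3), the two diagnosis
#'   flags (0/1), and `entry_present = TRUE`.
#' @export
read_diary <- function(path, covariates, window = observation_window()) {
  diary <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_diary(diary, covariates, window)
}

#' Validate an in-memory diary table
#'
#' @inheritParams read_diary
#' @param diary Data frame in the diary CSV layout.
#' @return Validated diary tibble (see [read_diary()]).
#' @export
validate_diary <- function(diary, covariates, window = observation_window()) {
  diary <- tibble::as_tibble(diary)
  unknown <- setdiff(names(diary), DIARY_COLUMNS)
  if (length(unknown)) {
    abort(paste0("unknown diary column(s): ", paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(DIARY_COLUMNS, names(diary))
  if (length(missing_cols)) {
    abort(paste0("diary lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  diary$child_id <- as.character(diary$child_id)
  diary$date <- as.Date(diary$date)

  for (col in c(ARI_SYMPTOMS, ARI_DX_FLAGS)) {
    v <- diary[[col]]
    if (anyNA(v) || !all(v == floor(v) & v >= 0)) {
      abort(sprintf("diary column '%s' must be non-negative integer codes", col))
    }
    hi <- if (col %in% ARI_DX_FLAGS) 1L else 3L
    if (any(v > hi)) {
      abort(sprintf("diary column '%s' has values above %d", col, hi))
    }
    diary[[col]] <- as.integer(v)
  }

  dup <- duplicated(diary[c("child_id", "date")])
  if (any(dup)) {
    keys <- diary[dup, c("child_id", "date")]
    abort(paste0("duplicate child-day rows: ",
                 paste(utils::head(paste(keys$child_id, keys$date), 10L),
                       collapse = "; ")))
  }

  unknown_children <- setdiff(diary$child_id, covariates$child_id)
  if (length(unknown_children)) {
    abort(paste0("diary contains child_id absent from covariates: ",
                 paste(unique(unknown_children), collapse = ", ")))
  }

  diary <- dplyr::left_join(
    diary,
    dplyr::select(covariates, "child_id", "birth_date"),
    by = "child_id"
  )
  diary$day_of_life <- as.integer(diary$date - diary$birth_date)
  out_of_window <- diary$day_of_life < window$start_day |
    diary$day_of_life > window$end_day
  if (any(out_of_window)) {
    inform(sprintf("dropping %d diary row(s) outside days %d-%d of life",
                   sum(out_of_window), window$start_day, window$end_day))
    diary <- diary[!out_of_window, , drop = FALSE]
  }
  diary$birth_date <- NULL
  diary$entry_present <- TRUE
  dplyr::arrange(
    dplyr::relocate(diary, "child_id", "date", "day_of_life"),
    .data$child_id, .data$day_of_life
  )
}

#' Write a diary table back to the CSV interface layout
#'
#' Drops the derived columns (`day_of_life`, `entry_present`) so that a
#' written file round-trips through [read_diary()] unchanged.
#'
#' @param diary Validated diary tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path) {
  out <- diary[, DIARY_COLUMNS, drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-child diary completeness
#'
#' Fraction of the observation window's days with a diary entry. Children in
#' `children` (default: those present in the diary) with no rows get 0.
#'
#' @param diary Validated diary tibble.
#' @param window An [observation_window()].
#' @param children Optional character vector of child ids defining the cohort
#'   universe (e.g. all children in the covariate table).
#' @return Tibble: `child_id`, `days_observed`, `completeness`.
#' @export
completeness <- function(diary, window = observation_window(), children = NULL) {
  children <- children %||% unique(diary$child_id)
  in_win <- diary[diary$day_of_life >= window$start_day &
                    diary$day_of_life <= window$end_day, , drop = FALSE]
  counts <- dplyr::count(in_win, .data$child_id, name = "days_observed")
  out <- dplyr::left_join(tibble::tibble(child_id = as.character(children)),
                          counts, by = "child_id")
  out$days_observed <- dplyr::coalesce(out$days_observed, 0L)
  out$completeness <- out$days_observed / window$n_days
  out
}

#' Apply the diary-completeness inclusion rule
#'
#' Children whose diary covers at least `window$completeness_threshold` of
#' the observation window (98% of 730 days by default) are included; the
#' rest are logged with their completeness.
#'
#' @param diary Validated diary tibble.
#' @param covariates Covariate table; defines the cohort universe.
#' @param window An [observation_window()]; its `completeness_threshold` is
#'   the inclusion cut-off.
#' @return A list with class `"ari_inclusion"`: `included` (character vector
#'   of child ids), `excluded` (tibble `child_id`, `days_observed`,
#'   `completeness`), `threshold`.
#' @export
apply_inclusion <- function(diary, covariates, window = observation_window()) {
  comp <- completeness(diary, window, children = covariates$child_id)
  keep <- comp$completeness >= window$completeness_threshold
  if (!any(keep)) {
    abort(sprintf(
      "no child reaches completeness %.2f; review the threshold or the data",
      window$completeness_threshold))
  }
  structure(
    list(included = comp$child_id[keep],
         excluded = comp[!keep, , drop = FALSE],
         threshold = window$completeness_threshold),
    class = "ari_inclusion"
  )
}

#' @export
print.ari_inclusion <- function(x, ...) {
  cat(sprintf("Inclusion at completeness >= %.2f: %d included, %d excluded\n",
              x$threshold, length(x$included), nrow(x$excluded)))
  invisible(x)
}

#' Restrict a diary to included children
#'
#' @param diary Validated diary tibble.
#' @param inclusion Result of [apply_inclusion()] (or a character vector of
#'   child ids).
#' @return The filtered diary tibble.
#' @export
filter_included <- function(diary, inclusion) {
  ids <- if (inherits(inclusion, "ari_inclusion")) inclusion$included else inclusion
  diary[diary$child_id %in% ids, , drop = FALSE]
}

#' Materialize the dense child-day grid
#'
#' Expands a diary to one row per child per window day, with
#' `entry_present = FALSE` and zeroed symptom columns on missing days (the
#' segmentation engine and prevalence curves work on this dense grid).
#'
#' @param diary Validated diary tibble.
#' @param window An [observation_window()].
#' @param children Optional child-id universe.
#' @return Dense diary tibble.
#' @export
materialize_days <- function(diary, window = observation_window(),
                             children = NULL) {
  children <- children %||% unique(diary$child_id)
  grid <- tidyr::expand_grid(
    child_id = as.character(children),
    day_of_life = seq(window$start_day, window$end_day)
  )
  dense <- dplyr::left_join(grid, diary, by = c("child_id", "day_of_life"))
  dense$entry_present <- dplyr::coalesce(dense$entry_present, FALSE)
  for (col in c(ARI_SYMPTOMS, ARI_DX_FLAGS)) {
    dense[[col]] <- dplyr::coalesce(dense[[col]], 0L)
  }
  dense
}
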
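# Crude and adjusted Poisson rate-ratio models of two-year ARI counts.

# Adjusted-model covariate set with treatment-coding references:
# breastfeeding 4-6 mo, vaginal birth, full term, 0 siblings, no daycare by
# 24 mo, male.
MODEL_COVARIATES <- c("breastfeeding", "daycare_entry", "birth_mode",
                      "birth_term", "sex", "older_siblings")

#' Build the model design frame
#'
#' Restricts the covariate table to the modelling covariates, applies
#' treatment coding with the standard reference levels, and drops children
#' with any missing covariate (complete-case rule, with a message). An
#' all-one-level covariate is dropped with a warning.
#'
#' @param covariates Covariate table (included children only).
#' @param variables Covariate columns to include.
#' @return Tibble `child_id` + factor columns, with attribute `n_dropped`
#'   (children removed for missing covariates).
#' @export
build_design <- function(covariates, variables = MODEL_COVARIATES) {
  missing_cols <- setdiff(variables, names(covariates))
  if (length(missing_cols)) {
    abort(paste0("covariates lack model column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  design <- covariates[, c("child_id", variables)]
  for (var in variables) {
    lv <- COVARIATE_LEVELS[[var]]
    vals <- as.character(design[[var]])
    if (!is.null(lv)) {
      bad <- setdiff(unique(vals[!is.na(vals)]), lv)
      if (length(bad)) {
        abort(sprintf("unseen level(s) in '%s': %s", var,
                      paste(bad, collapse = ", ")))
      }
      design[[var]] <- factor(vals, levels = lv)
    } else {
      design[[var]] <- factor(vals)
    }
  }
  cc <- complete.cases(design)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("dropping %d child(ren) with missing covariates (complete-case)",
                   n_dropped))
    design <- design[cc, , drop = FALSE]
  }
  for (var in variables) {
    design[[var]] <- droplevels(design[[var]])
    if (nlevels(design[[var]]) < 2) {
      warn(sprintf("covariate '%s' has a single observed level; dropped from design",
                   var))
      design[[var]] <- NULL
    }
  }
  attr(design, "n_dropped") <- n_dropped
  design
}

# Wald rate-ratio table from one fitted Poisson GLM.
rr_from_fit <- function(fit, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  keep <- names(est) != "(Intercept)"
  tibble::tibble(
    term = names(est)[keep],
    rr = unname(exp(est[keep])),
    conf_low = unname(exp(est[keep] - z * se[keep])),
    conf_high = unname(exp(est[keep] + z * se[keep]))
  )
}

# term label "sexfemale" -> covariate "sex", level "female"
term_map <- function(design, variables) {
  purrr::map_dfr(variables, function(var) {
    lv <- levels(design[[var]])
    tibble::tibble(covariate = var, level = lv,
                   term = paste0(var, lv),
                   is_reference = lv == lv[1])
  })
}

#' Fit crude and adjusted Poisson rate-ratio models
#'
#' Log-link Poisson GLM of per-child two-year episode counts. Crude mode
#' fits one covariate at a time; adjusted mode fits all covariates jointly.
#' Rate ratios are exponentiated coefficients with Wald confidence
#' intervals, `exp(b +/- z * SE)`. No exposure offset by default (all
#' included children are observed over essentially the full window); supply
#' `offset_days` (per-child observed days) for a `log(days)` offset
#' sensitivity analysis.
#'
#' @param counts Tibble `child_id`, `n_episodes` (non-negative integers).
#' @param covariates Covariate table for the same children.
#' @param mode `"both"` (default), `"crude"`, or `"adjusted"`.
#' @param variables Covariate columns to model (treatment coding, standard
#'   references).
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param offset_days Optional tibble `child_id`, `days_observed` enabling a
#'   log-exposure offset.
#' @return An object of class `"ari_rr_fit"`: `$table` (one row per
#'   covariate level: `covariate`, `level`, `is_reference`, `crude_rr`,
#'   `crude_low`, `crude_high`, `adj_rr`, `adj_low`, `adj_high`), `$models`
#'   (the glm fits), `$n`, `$mode`, `$offset`. Reference rows carry RR 1.
#' @export
fit_poisson <- function(counts, covariates, mode = c("both", "crude", "adjusted"),
                        variables = MODEL_COVARIATES, conf_level = 0.95,
                        offset_days = NULL) {
  mode <- match.arg(mode)
  if (any(counts$n_episodes < 0) || any(counts$n_episodes != floor(counts$n_episodes))) {
    abort("episode counts must be non-negative integers")
  }
  design <- build_design(covariates, variables)
  variables <- intersect(variables, names(design))
  df <- dplyr::inner_join(counts, design, by = "child_id")
  if (!is.null(offset_days)) {
    df <- dplyr::inner_join(df, offset_days, by = "child_id")
    df$.offset <- log(df$days_observed)
  } else {
    df$.offset <- 0
  }

  check_cells <- function(var) {
    tab <- table(df[[var]], df$n_episodes > 0)
    zero <- rownames(tab)[tab[, ncol(tab)] == 0]
    if (length(zero)) {
      warn(sprintf("covariate '%s': level(s) %s have no children with episodes (possible separation)",
                   var, paste(zero, collapse = ", ")))
    }
  }
  fit_one <- function(rhs) {
    f <- as.formula(paste("n_episodes ~", rhs))
    fit <- glm(f, data = df, family = poisson(link = "log"),
               offset = df$.offset)
    if (!fit$converged) {
      abort(sprintf("Poisson fit did not converge (formula: %s, %d iterations)",
                    rhs, fit$iter))
    }
    fit
  }

  tmap <- term_map(df, variables)
  models <- list()
  out <- tmap

  if (mode %in% c("both", "crude")) {
    crude <- purrr::map(variables, function(var) {
      check_cells(var)
      fit_one(var)
    })
    names(crude) <- variables
    models$crude <- crude
    crude_tab <- dplyr::bind_rows(purrr::map(crude, rr_from_fit, conf_level))
    out <- dplyr::left_join(out,
      dplyr::rename(crude_tab, crude_rr = "rr", crude_low = "conf_low",
                    crude_high = "conf_high"), by = "term")
    out$crude_rr[out$is_reference] <- 1
  }
  if (mode %in% c("both", "adjusted")) {
    adj <- fit_one(paste(variables, collapse = " + "))
    models$adjusted <- adj
    adj_tab <- rr_from_fit(adj, conf_level)
    out <- dplyr::left_join(out,
      dplyr::rename(adj_tab, adj_rr = "rr", adj_low = "conf_low",
                    adj_high = "conf_high"), by = "term")
    out$adj_rr[out$is_reference] <- 1
  }
  out$term <- NULL

  structure(
    list(table = out, models = models, n = nrow(df), mode = mode,
         conf_level = conf_level, offset = !is.null(offset_days),
         variables = variables),
    class = "ari_rr_fit"
  )
}

#' @export
print.ari_rr_fit <- function(x, ...) {
  cat(sprintf("Poisson rate ratios (%s, n = %d children%s)\n", x$mode, x$n,
              if (x$offset) ", log-days offset" else ""))
  print(x$table, n = Inf)
  invisible(x)
}

#' Tidy a fitted rate-ratio table
#'
#' One row per covariate level and model ("crude"/"adjusted"), broom-style.
#'
#' @param x An `"ari_rr_fit"`.
#' @param ... Unused.
#' @return Tibble: `covariate`, `level`, `model`, `estimate` (rate ratio),
#'   `conf.low`, `conf.high`, `is_reference`.
#' @export
tidy.ari_rr_fit <- function(x, ...) {
  tab <- x$table
  pieces <- list()
  if ("crude_rr" %in% names(tab)) {
    pieces$crude <- tibble::tibble(
      covariate = tab$covariate, level = tab$level, model = "crude",
      estimate = tab$crude_rr, conf.low = tab$crude_low,
      conf.high = tab$crude_high, is_reference = tab$is_reference)
  }
  if ("adj_rr" %in% names(tab)) {
    pieces$adjusted <- tibble::tibble(
      covariate = tab$covariate, level = tab$level, model = "adjusted",
      estimate = tab$adj_rr, conf.low = tab$adj_low,
      conf.high = tab$adj_high, is_reference = tab$is_reference)
  }
  dplyr::bind_rows(pieces)
}

#' Model-level summary of a rate-ratio fit
#'
#' @param x An `"ari_rr_fit"`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `mode`, `offset`, and (when an adjusted
#'   model was fitted) `logLik`, `deviance`, `df_residual`.
#' @export
glance.ari_rr_fit <- function(x, ...) {
  out <- tibble::tibble(n = x$n, mode = x$mode, offset = x$offset,
                        conf_level = x$conf_level)
  if (!is.null(x$models$adjusted)) {
    fit <- x$models$adjusted
    out$logLik <- as.numeric(logLik(fit))
    out$deviance <- fit$deviance
    out$df_residual <- fit$df.residual
  }
  out
}
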
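#' Nested covariate sets for the model ladder
#'
#' Four strictly nested covariate sets used for the tertile and
#' standardized linear models: demographics; plus lifestyle and adiposity;
#' plus dietary covariates and overall diet quality; plus insulin
#' resistance and blood lipids. Every report names the covariates used, so
#' alternative ladders can be supplied as a named list of character
#' vectors.
#'
#' @return A named list of covariate-name vectors (`model1`..`model4`),
#'   each a superset of the previous.
#' @export
model_ladder <- function() {
  m1 <- c("age", "sex")
  m2 <- c(m1, "bmi", "education", "smoking", "drinking", "exercise")
  m3 <- c(m2, "energy_kcal", "protein_g", "fiber_g", "sfa_g", "diet_quality")
  m4 <- c(m3, "homa_ir", "tc", "tg", "hdl", "ldl")
  list(model1 = m1, model2 = m2, model3 = m3, model4 = m4)
}

check_ladder <- function(ladder) {
  if (!is.list(ladder) || is.null(names(ladder)) || length(ladder) < 1) {
    abort("ladder must be a named list of covariate vectors",
          class = "aaci_error_config")
  }
  for (k in seq_along(ladder)[-1]) {
    if (!all(ladder[[k - 1]] %in% ladder[[k]])) {
      abort(
        sprintf("ladder models must be nested: '%s' is not a superset of '%s'",
                names(ladder)[k], names(ladder)[k - 1]),
        class = "aaci_error_config"
      )
    }
  }
  invisible(ladder)
}

#' Covariate set for single-serum-amino-acid quartile models
#'
#' The adjustment set for quartile models of one serum amino acid against
#' incident diabetes; note it includes the dietary index itself, so the
#' serum association is estimated conditional on the exposure.
#'
#' @return Character vector of covariate names.
#' @export
serum_model_covariates <- function() {
  c("age", "sex", "bmi", "education", "smoking", "drinking", "exercise",
    "energy_kcal", "protein_g", "fiber_g", "sfa_g", "diet_quality",
    "aaci", "tc", "tg", "hdl", "ldl", "homa_ir")
}

#' Ascertain incident type 2 diabetes
#'
#' A subject is a case if any qualifying component holds: self-reported
#' physician diagnosis, glucose-lowering treatment, fasting glucose >= 7.0
#' mmol/L, or 2-h post-load glucose >= 11.1 mmol/L. Missing components are
#' treated as non-qualifying; a subject with all four components missing is
#' indeterminate and flagged `NA` for exclusion.
#'
#' @param data Cohort data frame.
#' @param fasting,two_hour,self_report,treatment Column names of the four
#'   components; set a name to `NULL` if the column does not exist.
#' @param name Name of the output flag column.
#' @return `data` with a logical incident-case column added.
#' @export
#' @examples
#' d <- tibble::tibble(fasting_glucose = c(7.0, 5.1, 5.0),
#'                     two_hour_glucose = c(6.0, 11.1, 7.0))
#' ascertain_t2dm(d)$t2dm
ascertain_t2dm <- function(data, fasting = "fasting_glucose",
                           two_hour = "two_hour_glucose",
                           self_report = "t2dm_self_report",
                           treatment = "t2dm_treatment",
                           name = "t2dm") {
  comp <- function(colname) {
    if (!is.null(colname) && colname %in% names(data)) data[[colname]] else NULL
  }
  fg <- comp(fasting)
  g2 <- comp(two_hour)
  sr <- comp(self_report)
  tr <- comp(treatment)
  if (is.null(fg) && is.null(g2) && is.null(sr) && is.null(tr)) {
    abort("ascertainment needs at least one of the four case components",
          class = "aaci_error_schema")
  }
  n <- nrow(data)
  qualifies <- rep(FALSE, n)
  any_known <- rep(FALSE, n)
  add <- function(q, known) {
    qualifies <<- qualifies | (q %in% TRUE)
    any_known <<- any_known | known
  }
  if (!is.null(fg)) add(fg >= 7.0, !is.na(fg))
  if (!is.null(g2)) add(g2 >= 11.1, !is.na(g2))
  if (!is.null(sr)) add(sr %in% TRUE, !is.na(sr))
  if (!is.null(tr)) add(tr %in% TRUE, !is.na(tr))
  flag <- qualifies
  flag[!any_known] <- NA # indeterminate: nothing observed
  data[[name]] <- flag
  as_tibble(data)
}

#' Descriptive baseline table by exposure category
#'
#' Continuous variables are summarised as mean and SD per category with a
#' one-way ANOVA p-value; categorical (logical or factor) variables as
#' count and percentage with a chi-square p-value.
#'
#' @param data Cohort data frame.
#' @param by Name of the grouping factor (default `"tertile"`).
#' @param vars Variables to summarise; defaults to every column except
#'   `subject_id` and the grouping variable.
#' @return A long tibble: `variable`, `type`, one row per category with
#'   `mean`, `sd` (continuous) or `n_level`, `pct` (categorical), `n`, and
#'   the omnibus `p_value` repeated within variable.
#' @export
baseline_table <- function(data, by = "tertile", vars = NULL) {
  check_columns(data, by, "cohort table")
  g <- if (is.factor(data[[by]])) data[[by]] else factor(data[[by]])
  if (any(table(g) == 0)) {
    abort("baseline_table: empty exposure category",
          class = "aaci_error_degenerate")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(data), c("subject_id", by))
  }
  rows <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) {
      p <- tryCatch(
        summary(aov(x ~ g))[[1]][["Pr(>F)"]][1],
        error = function(e) NA_real_
      )
      tibble(
        variable = v, type = "continuous", category = levels(g),
        n = as.integer(table(g)),
        mean = as.numeric(tapply(x, g, mean, na.rm = TRUE)),
        sd = as.numeric(tapply(x, g, sd, na.rm = TRUE)),
        n_level = NA_integer_, pct = NA_real_, p_value = p
      )
    } else {
      x <- if (is.numeric(x)) x > 0 else x
      tab <- table(g, x)
      p <- tryCatch(
        suppressWarnings(chisq.test(tab)$p.value),
        error = function(e) NA_real_
      )
      pos <- if (is.logical(x)) {
        as.integer(tapply(x, g, function(z) sum(z %in% TRUE)))
      } else {
        as.integer(tab[, ncol(tab)])
      }
      tibble(
        variable = v, type = "categorical", category = levels(g),
        n = as.integer(table(g)),
        mean = NA_real_, sd = NA_real_,
        n_level = pos, pct = 100 * pos / as.integer(table(g)),
        p_value = p
      )
    }
  })
  bind_rows(rows)
}

# shared categorical-exposure logistic engine: exposure categories against a
# binary outcome, Wald CIs, trend test via the ordinal category score
fit_category_logistic <- function(data, outcome, category, covariates,
                                  model_label, conf_level = 0.95) {
  vars <- c(outcome, category, covariates)
  check_columns(data, vars, "cohort table")
  cc <- complete.cases(data[vars])
  d <- data[cc, , drop = FALSE]
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("%s: %d row(s) dropped by listwise deletion",
                   model_label, n_dropped))
  }
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1, TRUE, FALSE))) {
    abort("outcome must be binary", class = "aaci_error_domain")
  }
  y <- as.integer(y)
  f <- droplevels(factor(d[[category]]))
  lev <- levels(f)
  if (length(lev) < 2) {
    abort("exposure has fewer than two observed categories",
          class = "aaci_error_degenerate")
  }
  counts <- tibble(
    category = lev,
    n = as.integer(table(f)),
    cases = as.integer(tapply(y, f, sum))
  )
  # categories with no case-control contrast are non-estimable; the model is
  # fitted without their rows so the remaining contrasts stay interpretable
  bad <- counts$category[-1][counts$cases[-1] == 0 |
                              counts$cases[-1] == counts$n[-1]]
  keep <- !(as.character(f) %in% bad)
  d_fit <- d[keep, , drop = FALSE]
  f_fit <- droplevels(factor(d_fit[[category]]))
  rhs <- paste(c(".cat_", covariates), collapse = " + ")
  d_fit$.cat_ <- f_fit
  d_fit$.y_ <- y[keep]
  fit <- fit_logistic_checked(
    as.formula(paste(".y_ ~", rhs)), d_fit, model_label
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  cat_terms <- paste0(".cat_", levels(f_fit)[-1])

  res <- counts |>
    mutate(
      model = model_label,
      estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      p_value = NA_real_, reference = FALSE,
      note = ifelse(.data$category %in% bad, "non-estimable", NA_character_)
    )
  res$reference[1] <- TRUE
  res$estimate[1] <- 1
  for (k in seq_along(cat_terms)) {
    lab <- levels(f_fit)[-1][k]
    i <- match(lab, res$category)
    b <- est[[cat_terms[k]]]
    s <- se[[cat_terms[k]]]
    res$estimate[i] <- exp(b)
    res$conf_low[i] <- exp(b - zq * s)
    res$conf_high[i] <- exp(b + zq * s)
    res$p_value[i] <- 2 * pnorm(-abs(b / s))
  }

  # trend: refit with the ordinal category score entered as one linear term
  d$.score_ <- as.integer(f)
  d$.y_ <- y
  rhs_tr <- paste(c(".score_", covariates), collapse = " + ")
  fit_tr <- fit_logistic_checked(
    as.formula(paste(".y_ ~", rhs_tr)), d, paste0(model_label, " (trend)")
  )
  b_tr <- coef(fit_tr)[[".score_"]]
  s_tr <- sqrt(diag(vcov(fit_tr)))[[".score_"]]
  p_trend <- 2 * pnorm(-abs(b_tr / s_tr))

  list(
    table = select(res, "model", "category", "n", "cases", "estimate",
                   "conf_low", "conf_high", "p_value", "reference", "note"),
    p_trend = p_trend, trend_coef = b_tr, n_used = nrow(d),
    covariates = covariates
  )
}

fit_logistic_checked <- function(formula, data, label) {
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || sep_warn || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    abort(
      sprintf(
        "%s: logistic fit failed (%s); largest |coefficient| = %.2f",
        label,
        if (sep_warn) "quasi-complete separation" else "non-convergence",
        max(abs(coef(fit)), na.rm = TRUE)
      ),
      class = "aaci_error_fit"
    )
  }
  fit
}

#' Tertile logistic models for incident diabetes
#'
#' Fits one logistic regression per ladder model with the exposure tertile
#' as a factor (lowest tertile as reference) plus the model's covariates.
#' Exponentiated coefficients with Wald confidence intervals are reported;
#' they are odds ratios from a logistic model, labelled "RR" in the
#' `estimate` column's documentation following common cohort-study usage.
#' The trend p-value comes from refitting with the ordinal tertile score
#' (1, 2, 3) entered as a single linear term. Rows with missing model
#' variables are removed listwise (with a message). A category with no
#' cases (or no non-cases) is reported as non-estimable.
#'
#' @param data Cohort data frame with the outcome, the exposure factor and
#'   the covariates.
#' @param outcome Binary outcome column (default `"t2dm"`).
#' @param exposure Categorical exposure column (default `"tertile"`).
#' @param ladder Named list of nested covariate sets, see [model_ladder()].
#' @param models Which ladder entries to fit (default all).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble of class `aaci_assoc`: one row per model x category
#'   with `n`, `cases`, `estimate` (reference exactly 1), `conf_low`,
#'   `conf_high`, `p_value`; per-model trend p-values are available via
#'   [glance()] and in the `"p_trend"` attribute.
#' @export
fit_tertile_logistic <- function(data, outcome = "t2dm",
                                 exposure = "tertile",
                                 ladder = model_ladder(),
                                 models = names(ladder),
                                 conf_level = 0.95) {
  check_ladder(ladder)
  fits <- purrr::map(models, function(m) {
    fit_category_logistic(data, outcome, exposure, ladder[[m]], m, conf_level)
  })
  new_assoc(fits, models, outcome, exposure)
}

#' Quartile logistic model for one serum amino acid
#'
#' Splits one serum amino acid at its cohort-specific quartiles and fits a
#' logistic model for incident diabetes with quartile 1 as reference. The
#' default adjustment set ([serum_model_covariates()]) includes the dietary
#' index itself.
#'
#' @param data Cohort data frame; the serum column is `paste0("serum_", aa)`
#'   unless `aa` already carries the prefix.
#' @param aa Amino-acid name, e.g. `"valine"`.
#' @param outcome Binary outcome column.
#' @param covariates Adjustment set.
#' @param conf_level Confidence level for Wald intervals.
#' @return An `aaci_assoc` tibble as in [fit_tertile_logistic()].
#' @export
serum_quartile_logistic <- function(data, aa, outcome = "t2dm",
                                    covariates = serum_model_covariates(),
                                    conf_level = 0.95) {
  col <- if (startsWith(aa, "serum_")) aa else paste0("serum_", aa)
  check_columns(data, col, "cohort table")
  cuts <- quantile(data[[col]], c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  if (length(unique(cuts)) < 3) {
    abort(sprintf("degenerate quartiles for %s", col),
          class = "aaci_error_degenerate")
  }
  data$.quartile_ <- cut(data[[col]], breaks = c(-Inf, cuts, Inf),
                         labels = paste0("Q", 1:4), right = TRUE)
  fit <- fit_category_logistic(data, outcome, ".quartile_", covariates,
                               col, conf_level)
  out <- new_assoc(list(fit), col, outcome, col)
  attr(out, "cutpoints") <- unname(cuts)
  out
}

new_assoc <- function(fits, models, outcome, exposure) {
  tab <- bind_rows(purrr::map(fits, "table"))
  out <- structure(
    tab,
    class = c("aaci_assoc", class(tab)),
    p_trend = tibble(
      model = models,
      p_trend = purrr::map_dbl(fits, "p_trend"),
      trend_coef = purrr::map_dbl(fits, "trend_coef"),
      n = purrr::map_int(fits, "n_used")
    ),
    covariates = setNames(purrr::map(fits, "covariates"), models),
    outcome = outcome, exposure = exposure
  )
  out
}

#' @method tidy aaci_assoc
#' @export
tidy.aaci_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "aaci_assoc")
  attr(out, "p_trend") <- NULL
  attr(out, "covariates") <- NULL
  as_tibble(out)
}

#' @method glance aaci_assoc
#' @export
glance.aaci_assoc <- function(x, ...) {
  attr(x, "p_trend")
}

#' @method print aaci_assoc
#' @export
print.aaci_assoc <- function(x, ...) {
  cat(sprintf("<association of %s with %s>\n", attr(x, "exposure"),
              attr(x, "outcome")))
  print(tidy(x), ...)
  pt <- attr(x, "p_trend")
  cat("p for trend:",
      paste(sprintf("%s = %.4g", pt$model, pt$p_trend), collapse = ", "),
      "\n")
  invisible(x)
}

#' Standardized linear association of the index with continuous outcomes
#'
#' For each (outcome, model) pair, the exposure and the outcome are
#' z-scored within the complete-case analysis sample, then the outcome is
#' regressed on the standardized exposure plus the model's (unstandardized)
#' covariates. The reported `beta` is the standardized coefficient of the
#' exposure. Significance stars mark p < 0.05 (`*`) and p < 0.01 (`**`);
#' no multiplicity correction is applied, mirroring the convention of
#' reporting raw p-values across a serum amino-acid panel.
#'
#' @param data Cohort data frame.
#' @param outcomes Character vector of continuous outcome columns (e.g.
#'   `serum_*` columns, or `"hba1c"`).
#' @param exposure Continuous exposure column (default `"aaci"`).
#' @param ladder,models As in [fit_tertile_logistic()].
#' @return A tibble: `outcome`, `model`, `beta`, `se`, `statistic`,
#'   `p_value`, `n`, `stars`.
#' @export
fit_linear_std <- function(data, outcomes, exposure = "aaci",
                           ladder = model_ladder(), models = names(ladder)) {
  check_ladder(ladder)
  grid <- tidyr::expand_grid(outcome = outcomes, model = models)
  rows <- purrr::pmap(grid, function(outcome, model) {
    covs <- ladder[[model]]
    vars <- c(outcome, exposure, covs)
    check_columns(data, vars, "cohort table")
    d <- data[complete.cases(data[vars]), vars, drop = FALSE]
    d$.zx_ <- zscore(d[[exposure]], exposure)
    d$.zy_ <- zscore(d[[outcome]], outcome)
    f <- as.formula(paste(".zy_ ~", paste(c(".zx_", covs), collapse = " + ")))
    fit <- lm(f, data = d)
    sm <- summary(fit)$coefficients
    tibble(
      outcome = outcome, model = model,
      beta = sm[".zx_", 1], se = sm[".zx_", 2],
      statistic = sm[".zx_", 3], p_value = sm[".zx_", 4],
      n = nrow(d)
    )
  })
  bind_rows(rows) |>
    mutate(stars = dplyr::case_when(
      .data$p_value < 0.01 ~ "**",
      .data$p_value < 0.05 ~ "*",
      TRUE ~ ""
    ))
}

#' Food-group intake against the index
#'
#' For each food group: the Spearman correlation of daily intake with the
#' continuous index, plus mean intake per index tertile and a linear trend
#' p-value across the ordinal tertile score. Groups with constant intake
#' have an undefined correlation and are reported as `NA`.
#'
#' @param data Cohort data frame with `subject_id`, `aaci` and `tertile`.
#' @param groups Output of [food_group_profile()] for the same subjects.
#' @return A tibble: `food_group`, `rho`, `p_value`, `mean_T1..mean_T3`,
#'   `p_trend`.
#' @export
food_group_trend <- function(data, groups) {
  check_columns(data, c("subject_id", "aaci", "tertile"), "cohort table")
  merged <- inner_join(
    data[c("subject_id", "aaci", "tertile")],
    groups, by = "subject_id"
  )
  gvars <- setdiff(names(groups), "subject_id")
  score <- as.integer(factor(merged$tertile))
  rows <- purrr::map(gvars, function(g) {
    x <- merged[[g]]
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      return(tibble(food_group = g, rho = NA_real_, p_value = NA_real_,
                    mean_T1 = mean(x[score == 1], na.rm = TRUE),
                    mean_T2 = mean(x[score == 2], na.rm = TRUE),
                    mean_T3 = mean(x[score == 3], na.rm = TRUE),
                    p_trend = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x, merged$aaci, method = "spearman", exact = FALSE)
    )
    tr <- summary(lm(x ~ score))$coefficients
    tibble(
      food_group = g,
      rho = unname(ct$estimate), p_value = ct$p.value,
      mean_T1 = mean(x[score == 1], na.rm = TRUE),
      mean_T2 = mean(x[score == 2], na.rm = TRUE),
      mean_T3 = mean(x[score == 3], na.rm = TRUE),
      p_trend = if (nrow(tr) > 1) tr[2, 4] else NA_real_
    )
  })
  bind_rows(rows)
}
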
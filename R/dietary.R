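#' Convert FFQ records to daily nutrient intakes
#'
#' Multiplies each food-frequency record's consumption (events/day x g/event)
#' by the food's per-100 g nutrient content and sums over foods, yielding
#' one row per subject with daily amino-acid intakes (mg/day) and
#' macronutrient covariates.
#'
#' @param records Long-format FFQ data frame with columns `subject_id`,
#'   `food_id`, `frequency_per_day` (events/day) and `portion_g` (g/event).
#' @param composition Food-composition table with columns `food_id`,
#'   `food_group`, per-100 g nutrient columns `energy_kcal`, `protein_g`,
#'   `fiber_g`, `sfa_g`, and one `<code>_mg` column per scored amino acid
#'   (e.g. `ile_mg`, ..., `trp_mg`).
#' @param subjects Optional vector of subject ids; subjects with no records
#'   receive all-zero profiles.
#' @return A tibble with `subject_id`, one column per amino-acid code
#'   (mg/day) and `energy_kcal`, `protein_g`, `fiber_g`, `sfa_g` (per day).
#' @export
ffq_to_intake <- function(records, composition, subjects = NULL) {
  check_columns(records, c("subject_id", "food_id", "frequency_per_day",
                           "portion_g"), "FFQ table")
  codes <- unname(scored_amino_acids())
  aa_cols <- paste0(codes, "_mg")
  macro_cols <- c("energy_kcal", "protein_g", "fiber_g", "sfa_g")
  check_columns(composition, c("food_id", aa_cols, macro_cols),
                "composition table")

  if (any(records$frequency_per_day < 0, na.rm = TRUE) ||
      any(records$portion_g < 0, na.rm = TRUE)) {
    abort("FFQ table: frequency and portion must be non-negative",
          class = "aaci_error_domain")
  }
  unknown <- setdiff(unique(records$food_id), composition$food_id)
  if (length(unknown) > 0) {
    abort(
      sprintf("FFQ table: food ids missing from composition table: %s",
              paste(unknown, collapse = ", ")),
      class = "aaci_error_schema"
    )
  }

  nutrient_cols <- c(aa_cols, macro_cols)
  comp <- composition[match(records$food_id, composition$food_id), ]
  # daily grams consumed of this item, scaled by per-100 g content
  grams <- records$frequency_per_day * records$portion_g
  contrib <- as.matrix(comp[nutrient_cols]) * (grams / 100)

  ids <- factor(records$subject_id)
  sums <- rowsum(contrib, ids)
  out <- tibble(subject_id = rownames(sums))
  out <- bind_cols(out, as_tibble(sums))
  names(out) <- c("subject_id", codes, macro_cols)

  if (!is.null(subjects)) {
    missing_ids <- setdiff(as.character(subjects), out$subject_id)
    if (length(missing_ids) > 0) {
      zeros <- as_tibble(matrix(
        0, nrow = length(missing_ids), ncol = length(nutrient_cols),
        dimnames = list(NULL, c(codes, macro_cols))
      ))
      out <- bind_rows(out, bind_cols(tibble(subject_id = missing_ids), zeros))
    }
    out <- out[match(as.character(subjects), out$subject_id), ]
  }
  out
}

#' Per-subject daily intake by food group
#'
#' @inheritParams ffq_to_intake
#' @return A tibble with `subject_id` and one column per food group
#'   (g/day); groups never consumed by a subject are 0.
#' @export
food_group_profile <- function(records, composition, subjects = NULL) {
  check_columns(records, c("subject_id", "food_id", "frequency_per_day",
                           "portion_g"), "FFQ table")
  check_columns(composition, c("food_id", "food_group"), "composition table")
  unknown <- setdiff(unique(records$food_id), composition$food_id)
  if (length(unknown) > 0) {
    abort(
      sprintf("FFQ table: food ids missing from composition table: %s",
              paste(unknown, collapse = ", ")),
      class = "aaci_error_schema"
    )
  }
  all_groups <- sort(unique(composition$food_group))
  out <- records |>
    mutate(
      grams = .data$frequency_per_day * .data$portion_g,
      food_group = composition$food_group[
        match(.data$food_id, composition$food_id)
      ]
    ) |>
    group_by(.data$subject_id, .data$food_group) |>
    summarise(grams = sum(.data$grams), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "food_group", values_from = "grams", values_fill = 0
    )
  for (g in setdiff(all_groups, names(out))) out[[g]] <- 0
  out <- out[c("subject_id", all_groups)]
  if (!is.null(subjects)) {
    idx <- match(as.character(subjects), out$subject_id)
    out <- out[idx, ]
    out$subject_id <- as.character(subjects)
    out[is.na(idx), all_groups] <- 0
  }
  as_tibble(out)
}

#' Convert common FFQ frequency encodings to events per day
#'
#' @param n Number of consumption events per period.
#' @param per Period of the encoding: `"day"`, `"week"` (divides by 7) or
#'   `"month"` (divides by 30.44, the mean Gregorian month length).
#' @return Events per day.
#' @export
#' @examples
#' frequency_per_day(3, "week")
frequency_per_day <- function(n, per = c("day", "week", "month")) {
  per <- match.arg(per)
  n / switch(per, day = 1, week = 7, month = 30.44)
}

#' Cohort inclusion criteria
#'
#' Defaults match the study design this package implements: adults aged
#' 20-74 with daily energy intake between 500 and 4500 kcal, free of
#' diabetes at baseline, with serum amino acids measured.
#'
#' @param age_range Inclusive age range in years.
#' @param energy_range Inclusive energy range in kcal/day.
#' @param require_diabetes_free_baseline Exclude subjects with baseline
#'   diabetes (column `t2dm_baseline`).
#' @param require_serum_aas Exclude subjects with any missing `serum_*`
#'   column.
#' @return A list of class `aaci_inclusion`.
#' @export
inclusion_criteria <- function(age_range = c(20, 74),
                               energy_range = c(500, 4500),
                               require_diabetes_free_baseline = TRUE,
                               require_serum_aas = TRUE) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2],
            length(energy_range) == 2, energy_range[1] <= energy_range[2])
  structure(
    list(
      age_range = age_range, energy_range = energy_range,
      require_diabetes_free_baseline = require_diabetes_free_baseline,
      require_serum_aas = require_serum_aas
    ),
    class = "aaci_inclusion"
  )
}

#' Apply cohort inclusion criteria
#'
#' Filters the cohort and records an exclusion ledger. Criteria are applied
#' in a fixed order — age, energy too low, energy too high, baseline
#' diabetes, missing serum amino acids — and each excluded subject is
#' counted once, under the first criterion it fails, so ledgers are
#' deterministic and the counts plus the retained total always equal the
#' input count.
#'
#' @param data Cohort data frame with columns `age`, `energy_kcal` and,
#'   depending on the criteria, `t2dm_baseline` and `serum_*` columns.
#' @param criteria An [inclusion_criteria()] object.
#' @return The retained rows as a tibble, with the ledger in the
#'   `"exclusions"` attribute (see [exclusion_ledger()]).
#' @export
apply_inclusion <- function(data, criteria = inclusion_criteria()) {
  check_columns(data, c("age", "energy_kcal"), "cohort table")
  n_in <- nrow(data)

  fail_age <- data$age < criteria$age_range[1] |
    data$age > criteria$age_range[2]
  fail_elo <- data$energy_kcal < criteria$energy_range[1]
  fail_ehi <- data$energy_kcal > criteria$energy_range[2]
  fail_dm <- if (criteria$require_diabetes_free_baseline) {
    check_columns(data, "t2dm_baseline", "cohort table")
    data$t2dm_baseline %in% TRUE
  } else rep(FALSE, n_in)
  serum_cols <- grep("^serum_", names(data), value = TRUE)
  fail_serum <- if (criteria$require_serum_aas && length(serum_cols) > 0) {
    !complete.cases(data[serum_cols])
  } else rep(FALSE, n_in)

  fail_age[is.na(fail_age)] <- TRUE
  fail_elo[is.na(fail_elo)] <- TRUE
  fail_ehi[is.na(fail_ehi)] <- TRUE

  # first-failure attribution in the fixed precedence order
  reason <- rep(NA_character_, n_in)
  reason[fail_serum] <- "missing_serum_aas"
  reason[fail_dm] <- "baseline_diabetes"
  reason[fail_ehi] <- "energy_high"
  reason[fail_elo] <- "energy_low"
  reason[fail_age] <- "age"

  keep <- is.na(reason)
  reasons <- c("age", "energy_low", "energy_high", "baseline_diabetes",
               "missing_serum_aas")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1), USE.NAMES = FALSE)
  ledger <- tibble(reason = reasons, n = counts)
  out <- as_tibble(data[keep, ])
  if (nrow(out) == 0) {
    inform("apply_inclusion: no subjects retained")
  }
  attr(out, "exclusions") <- ledger
  attr(out, "n_input") <- n_in
  out
}

#' Exclusion ledger of a filtered cohort
#'
#' @param data The tibble returned by [apply_inclusion()].
#' @return A tibble with per-reason exclusion counts.
#' @export
exclusion_ledger <- function(data) {
  ledger <- attr(data, "exclusions")
  if (is.null(ledger)) {
    abort("no exclusion ledger attached; was this produced by apply_inclusion()?",
          class = "aaci_error_config")
  }
  ledger
}
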
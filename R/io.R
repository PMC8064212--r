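#' Column dictionary for a cohort table
#'
#' The expected schema of a wide cohort CSV: one row per subject, serum
#' amino-acid columns prefixed `serum_`. Each entry gives the type and,
#' where physiology dictates one, a valid range.
#'
#' @return A tibble with columns `column`, `type`, `min`, `max`,
#'   `required`.
#' @export
cohort_schema <- function() {
  num <- function(column, min = NA, max = NA, required = TRUE) {
    tibble(column = column, type = "numeric", min = min, max = max,
           required = required)
  }
  flag <- function(column, required = TRUE) {
    tibble(column = column, type = "flag", min = NA, max = NA,
           required = required)
  }
  bind_rows(
    tibble(column = "subject_id", type = "id", min = NA, max = NA,
           required = TRUE),
    num("age", 0, 120), num("bmi", 10, 80), flag("sex"),
    flag("education"), flag("smoking"), flag("drinking"), flag("exercise"),
    num("energy_kcal", 0), num("protein_g", 0), num("fiber_g", 0),
    num("sfa_g", 0), num("diet_quality"),
    num("aaci", 0),
    bind_rows(purrr::map(
      paste0("serum_", serum_reference()$aa),
      function(cl) num(cl)
    )),
    num("fasting_glucose", 0, required = FALSE),
    num("two_hour_glucose", 0, required = FALSE),
    num("hba1c", 0, required = FALSE),
    num("fasting_insulin", 0, required = FALSE),
    num("homa_ir", 0), num("tc", 0), num("tg", 0), num("hdl", 0),
    num("ldl", 0),
    flag("t2dm"), flag("t2dm_baseline", required = FALSE)
  )
}

#' Validate a table against a schema
#'
#' Collects every violation — missing required columns, non-numeric
#' content, out-of-range values with row indices — rather than failing at
#' the first.
#'
#' @param data The loaded table.
#' @param schema A schema tibble as returned by [cohort_schema()].
#' @return A tibble of violations (`column`, `row`, `problem`); zero rows
#'   means the table is clean.
#' @export
validate_schema <- function(data, schema = cohort_schema()) {
  out <- list()
  for (i in seq_len(nrow(schema))) {
    s <- schema[i, ]
    cl <- s$column
    if (!cl %in% names(data)) {
      if (s$required) {
        out[[length(out) + 1]] <- tibble(
          column = cl, row = NA_integer_, problem = "missing column"
        )
      }
      next
    }
    x <- data[[cl]]
    if (s$type == "numeric") {
      if (!is.numeric(x)) {
        out[[length(out) + 1]] <- tibble(
          column = cl, row = NA_integer_, problem = "not numeric"
        )
        next
      }
      if (!is.na(s$min)) {
        bad <- which(x < s$min)
        if (length(bad) > 0) {
          out[[length(out) + 1]] <- tibble(
            column = cl, row = bad,
            problem = sprintf("below minimum %s", format(s$min))
          )
        }
      }
      if (!is.na(s$max)) {
        bad <- which(x > s$max)
        if (length(bad) > 0) {
          out[[length(out) + 1]] <- tibble(
            column = cl, row = bad,
            problem = sprintf("above maximum %s", format(s$max))
          )
        }
      }
    } else if (s$type == "flag") {
      ok <- is.logical(x) || all(x %in% c(0, 1, NA))
      if (!ok) {
        out[[length(out) + 1]] <- tibble(
          column = cl, row = NA_integer_, problem = "not a 0/1 or logical flag"
        )
      }
    }
  }
  if (length(out) == 0) {
    tibble(column = character(), row = integer(), problem = character())
  } else {
    bind_rows(out)
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes score -> inclusion filters -> associations -> mediation on
#' tabular inputs and writes every stage output plus a provenance manifest
#' (input file hashes, cutpoints, seed, package version, output files) to
#' the output directory. Deterministic stages are bit-identical on rerun
#' with the same inputs and seed.
#'
#' The configuration is a named list (or path to a YAML file with the same
#' structure):
#'
#' * `paths`: `cohort` (required; wide CSV per [cohort_schema()], minus
#'   `aaci` if intakes are supplied), and either `intake` or both `ffq`
#'   and `composition`; optional `pattern` CSV.
#' * `out_dir`: output directory (created if needed).
#' * `seed`: global seed for the stochastic stages.
#' * `cutpoints`: optional explicit tertile cutpoints (length-2 numeric).
#' * `analyses`: named logical toggles `baseline`, `association`, `serum`,
#'   `mediation` (all default `TRUE`).
#' * `models`: which ladder models to fit (default all of
#'   [model_ladder()]).
#' * `mediation`: fields passed to [mediation_spec()].
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the analysis results, the provenance
#'   manifest and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  paths <- config$paths %||% list()
  if (is.null(paths$cohort)) {
    abort("config$paths$cohort is required", class = "aaci_error_config")
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  toggles <- config$analyses %||% list()
  on_ <- function(nm) isTRUE(toggles[[nm]] %||% TRUE)

  input_files <- unlist(paths)
  missing_files <- input_files[!file.exists(input_files)]
  if (length(missing_files) > 0) {
    abort(sprintf("input file(s) not found: %s",
                  paste(missing_files, collapse = ", ")),
          class = "aaci_error_io")
  }
  input_md5 <- tools::md5sum(input_files)

  pattern <- if (!is.null(paths$pattern)) read_hraap(paths$pattern) else
    hraap_default()
  cohort <- readr::read_csv(paths$cohort, show_col_types = FALSE)

  stage <- "score"
  results <- list()
  outputs <- character()
  emit <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tbl, p)
    outputs <<- c(outputs, p)
    p
  }
  run_stage <- function(label, expr) {
    stage <<- label
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed at stage '%s': %s", label,
                    conditionMessage(e)),
            class = "aaci_error_pipeline")
    })
  }

  run_stage("score", {
    intake <- if (!is.null(paths$intake)) {
      readr::read_csv(paths$intake, show_col_types = FALSE)
    } else if (!is.null(paths$ffq) && !is.null(paths$composition)) {
      ffq_to_intake(
        readr::read_csv(paths$ffq, show_col_types = FALSE),
        readr::read_csv(paths$composition, show_col_types = FALSE)
      )
    } else {
      abort("need paths$intake, or paths$ffq plus paths$composition",
            class = "aaci_error_config")
    }
    idx <- compute_aaci(intake, pattern)
    cohort <- left_join(cohort, idx[c("subject_id", "aaci")],
                         by = "subject_id")
    cohort <- add_tertiles(cohort, cutpoints = config$cutpoints)
    results$aaci <- add_tertiles(idx, cutpoints = attr(cohort, "cutpoints"))
    emit(results$aaci, "aaci.csv")
  })

  run_stage("inclusion", {
    cohort <- apply_inclusion(cohort)
    results$exclusions <- exclusion_ledger(cohort)
    jsonlite::write_json(
      setNames(as.list(results$exclusions$n), results$exclusions$reason),
      file.path(out_dir, "exclusions.json"), auto_unbox = TRUE
    )
    outputs <- c(outputs, file.path(out_dir, "exclusions.json"))
  })

  models <- config$models %||% names(model_ladder())
  if (on_("baseline")) {
    run_stage("baseline", {
      results$baseline <- baseline_table(cohort)
      emit(results$baseline, "baseline.csv")
    })
  }
  if (on_("association")) {
    run_stage("association", {
      fit <- fit_tertile_logistic(cohort, models = models)
      results$association <- fit
      emit(tidy(fit), "tertile_association.csv")
      emit(glance(fit), "tertile_trend.csv")
    })
  }
  if (on_("serum")) {
    run_stage("serum", {
      serum_cols <- grep("^serum_", names(cohort), value = TRUE)
      results$serum <- fit_linear_std(
        cohort, outcomes = serum_cols,
        models = intersect(models, c("model1", "model2", "model3"))
      )
      emit(results$serum, "serum_associations.csv")
    })
  }
  if (on_("mediation")) {
    run_stage("mediation", {
      ms <- config$mediation %||% list()
      spec <- mediation_spec(
        exposure = ms$exposure %||% "aaci",
        mediators = ms$mediators %||% c("serum_valine",
                                        "serum_glutamic_acid",
                                        "serum_histidine"),
        outcome = ms$outcome %||% "t2dm",
        covariates = ms$covariates %||% model_ladder()$model3,
        n_bootstrap = ms$n_bootstrap %||% 1000,
        seed = seed,
        link = ms$link %||% "probit"
      )
      med <- mediate_aaci(cohort, spec)
      results$mediation <- med
      emit(tidy(med), "mediation_paths.csv")
      emit(med$effects, "mediation_effects.csv")
      jsonlite::write_json(
        list(paths = med$paths, effects = med$effects, n = med$n,
             n_boot_used = med$n_boot_used, link = spec$link),
        file.path(out_dir, "mediation.json"), auto_unbox = TRUE, digits = NA
      )
      outputs <- c(outputs, file.path(out_dir, "mediation.json"))
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("aaci")),
    seed = seed,
    inputs = as.list(input_md5),
    cutpoints = attr(cohort, "cutpoints"),
    outputs = basename(outputs)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, provenance = provenance,
                 outputs = c(outputs, file.path(out_dir, "provenance.json")),
                 cohort = cohort))
}
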
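#' Per-amino-acid satisfaction scores and the composition index
#'
#' For each subject, each scored amino acid receives a satisfaction score
#'
#' \deqn{q_i = \left| \frac{\mathrm{intake}_i / \mathrm{intake}_{Trp}}
#'   {\beta_i} - 1 \right|}
#'
#' the absolute relative deviation of the diet's amino-acid-to-tryptophan
#' ratio from the requirement pattern's ratio. The index is the sum of the
#' eleven scores (tryptophan's own term is identically zero). An index of 0
#' means the dietary amino-acid composition is exactly proportional to the
#' requirement pattern; larger values mean poorer adherence. The index is
#' invariant to rescaling all intakes by a common factor, so any consistent
#' intake unit may be used.
#'
#' @param intake A data frame with a `subject_id` column and one column per
#'   scored amino acid named by its three-letter code (`ile`, `leu`, `lys`,
#'   `met`, `phe`, `thr`, `trp`, `val`, `his`, `cys`, `tyr`), daily intakes
#'   in any consistent unit (conventionally mg/day). Intakes must be
#'   non-negative and tryptophan strictly positive.
#' @param pattern Requirement-pattern table, see [hraap_default()].
#' @return A tibble with `subject_id`, one `q_<code>` column per amino
#'   acid, and `aaci`, the summed index.
#' @export
#' @examples
#' intake <- tibble::tibble(
#'   subject_id = "s1", ile = 2100, leu = 4130, lys = 3150, met = 1120,
#'   phe = 1330, thr = 1610, trp = 420, val = 2730, his = 1050, cys = 420,
#'   tyr = 1330
#' )
#' compute_aaci(intake) # proportional to the default pattern: aaci = 0
compute_aaci <- function(intake, pattern = hraap_default()) {
  codes <- unname(scored_amino_acids())
  check_columns(intake, c("subject_id", codes), "intake table")
  br <- beta_ratios(pattern)

  mat <- as.matrix(intake[codes])
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("intake table: amino-acid intakes must be finite and non-negative",
          class = "aaci_error_domain")
  }
  trp <- mat[, "trp"]
  if (any(trp <= 0)) {
    bad <- intake$subject_id[trp <= 0]
    abort(
      sprintf(
        "zero or negative tryptophan intake for subject%s: %s",
        if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      class = "aaci_error_domain"
    )
  }

  beta <- setNames(br$beta, br$code)[codes]
  q <- abs(sweep(mat / trp, 2, beta, "/") - 1)
  q[, "trp"] <- 0 # ratio of tryptophan to itself is 1 and its beta is 1

  out <- tibble(subject_id = intake$subject_id)
  qtbl <- as_tibble(q)
  names(qtbl) <- paste0("q_", codes)
  out <- bind_cols(out, qtbl)
  out$aaci <- rowSums(q)
  out
}

#' Assign tertile categories
#'
#' Splits a continuous exposure at its 33.3%/66.7% sample quantiles
#' (linear-interpolation quantiles, R type 7), or at explicitly supplied
#' cutpoints. Intervals are half-open with a closed upper bound:
#' `(-Inf, c1]`, `(c1, c2]`, `(c2, Inf)`, so a value tied with a cutpoint
#' falls in the lower category. The cutpoints used are attached as the
#' `"cutpoints"` attribute so published boundaries can be reproduced as run
#' metadata.
#'
#' @param x Numeric vector of exposure values.
#' @param cutpoints Optional numeric pair of explicit cutpoints; when
#'   absent, empirical tertile cutpoints are computed from `x`.
#' @param labels Category labels, default `c("T1", "T2", "T3")`.
#' @return A factor the length of `x` with a `"cutpoints"` attribute.
#' @seealso [add_tertiles()] for the data-frame interface.
#' @export
#' @examples
#' t <- aaci_tertiles(c(1:9))
#' table(t)
#' attr(t, "cutpoints")
aaci_tertiles <- function(x, cutpoints = NULL, labels = c("T1", "T2", "T3")) {
  if (is.null(cutpoints)) {
    if (length(x) < 3 || length(unique(x[is.finite(x)])) < 3 ||
        is_degenerate(x)) {
      abort(
        "need at least 3 distinct values to compute tertile cutpoints; supply explicit cutpoints instead",
        class = "aaci_error_degenerate"
      )
    }
    cutpoints <- unname(quantile(x, c(1, 2) / 3, na.rm = TRUE, type = 7))
  }
  if (length(cutpoints) != 2 || cutpoints[1] > cutpoints[2]) {
    abort("cutpoints must be an ordered numeric pair",
          class = "aaci_error_config")
  }
  if (diff(cutpoints) <= 1e-12 + 1e-10 * max(abs(cutpoints))) {
    abort("degenerate tertiles: the two cutpoints coincide",
          class = "aaci_error_degenerate")
  }
  f <- cut(x, breaks = c(-Inf, cutpoints, Inf), labels = labels, right = TRUE)
  attr(f, "cutpoints") <- cutpoints
  f
}

#' Add a tertile column to a cohort table
#'
#' @param data A data frame containing the exposure column.
#' @param var Name of the exposure column (default `"aaci"`).
#' @param cutpoints Optional explicit cutpoints passed to [aaci_tertiles()].
#' @param name Name of the new column (default `"tertile"`).
#' @return `data` with the tertile factor added; the cutpoints used are
#'   stored in the `"cutpoints"` attribute of the returned tibble.
#' @export
add_tertiles <- function(data, var = "aaci", cutpoints = NULL,
                         name = "tertile") {
  check_columns(data, var, "cohort table")
  f <- aaci_tertiles(data[[var]], cutpoints = cutpoints)
  data[[name]] <- f
  out <- as_tibble(data)
  attr(out, "cutpoints") <- attr(f, "cutpoints")
  out
}

#' Write index results with a provenance sidecar
#'
#' Writes the per-subject satisfaction scores and index as CSV and a JSON
#' sidecar recording the requirement-pattern file hash (when a path is
#' given) and the tertile cutpoints used.
#'
#' @param result Output of [compute_aaci()], optionally after
#'   [add_tertiles()].
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param pattern_path Optional path of the pattern file used, hashed into
#'   the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_aaci <- function(result, path, pattern_path = NULL) {
  readr::write_csv(result, path)
  sidecar <- list(
    pattern_file = pattern_path,
    pattern_md5 = if (!is.null(pattern_path)) {
      unname(tools::md5sum(pattern_path))
    },
    cutpoints = attr(result, "cutpoints"),
    n_subjects = nrow(result)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar)
}
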
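#' Amino acids scored by the composition index
#'
#' The index scores eleven amino acids: the nine essential amino acids plus
#' the two conditionally essential ones (cysteine and tyrosine). Tryptophan
#' is among the eleven and serves as the ratio denominator, so its own
#' satisfaction term is identically zero.
#'
#' @return A named character vector mapping full amino-acid names to the
#'   three-letter column codes used throughout the package.
#' @export
#' @examples
#' scored_amino_acids()
scored_amino_acids <- function() {
  c(
    isoleucine = "ile", leucine = "leu", lysine = "lys",
    methionine = "met", phenylalanine = "phe", threonine = "thr",
    tryptophan = "trp", valine = "val", histidine = "his",
    cysteine = "cys", tyrosine = "tyr"
  )
}

#' Default human requirement amino acid pattern
#'
#' Adult requirement levels in mg per g protein, following the WHO/FAO/UNU
#' (2007) adult pattern. The combined sulphur amino acid requirement
#' (22 mg/g) is split into methionine 16 and cysteine 6 as sub-listed in the
#' report; the combined aromatic requirement (38 mg/g) has no published
#' split and is divided evenly between phenylalanine and tyrosine (19/19) —
#' a documented assumption that users may override by supplying their own
#' pattern table (see [read_hraap()]).
#'
#' Because the index is built from ratios of ratios, only the relative
#' proportions of the levels matter; any consistent unit is acceptable.
#'
#' @return A tibble with columns `amino_acid` (full name) and `level`
#'   (mg per g protein).
#' @export
#' @examples
#' hraap_default()
hraap_default <- function() {
  tibble(
    amino_acid = c(
      "histidine", "isoleucine", "leucine", "lysine", "methionine",
      "cysteine", "phenylalanine", "tyrosine", "threonine", "tryptophan",
      "valine"
    ),
    level = c(15, 30, 59, 45, 16, 6, 19, 19, 23, 6, 39)
  )
}

# normalize user-supplied amino-acid labels (full names or 3-letter codes,
# any case) to the canonical codes; unknown labels abort
canonical_aa_codes <- function(labels, where = "pattern") {
  vocab <- scored_amino_acids()
  lab <- tolower(trimws(labels))
  out <- character(length(lab))
  out[lab %in% vocab] <- lab[lab %in% vocab]
  full <- match(lab, names(vocab))
  out[!is.na(full)] <- vocab[full[!is.na(full)]]
  bad <- labels[out == ""]
  if (length(bad) > 0) {
    abort(
      sprintf(
        "%s: unrecognized amino acid name%s: %s (expected one of: %s)",
        where, if (length(bad) > 1) "s" else "",
        paste(unique(bad), collapse = ", "),
        paste(names(vocab), collapse = ", ")
      ),
      class = "aaci_error_config"
    )
  }
  out
}

validate_pattern <- function(pattern, where = "pattern") {
  check_columns(pattern, c("amino_acid", "level"), where)
  pattern <- as_tibble(pattern)
  pattern$code <- canonical_aa_codes(pattern$amino_acid, where)
  if (anyDuplicated(pattern$code)) {
    abort(sprintf("%s: duplicated amino acid entries", where),
          class = "aaci_error_config")
  }
  bad <- pattern$amino_acid[!is.finite(pattern$level) | pattern$level <= 0]
  if (length(bad) > 0) {
    abort(
      sprintf("%s: non-positive requirement level for: %s",
              where, paste(bad, collapse = ", ")),
      class = "aaci_error_config"
    )
  }
  miss <- setdiff(unname(scored_amino_acids()), pattern$code)
  if (length(miss) > 0) {
    abort(
      sprintf("%s: missing amino acid%s: %s", where,
              if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")),
      class = "aaci_error_config"
    )
  }
  pattern
}

#' Read a requirement-pattern table from CSV
#'
#' Expects a two-column CSV with a header, `amino_acid,level`. Names are
#' matched case-insensitively against the canonical vocabulary (full names
#' or three-letter codes); all eleven scored amino acids, tryptophan among
#' them, must be present with strictly positive levels.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `amino_acid` and `level`.
#' @export
read_hraap <- function(path) {
  pattern <- readr::read_csv(path, show_col_types = FALSE)
  validate_pattern(pattern, where = sprintf("pattern file '%s'", path))
  as_tibble(pattern[c("amino_acid", "level")])
}

#' Reference composition ratios to tryptophan
#'
#' Divides each amino acid's requirement level by the tryptophan requirement
#' level, yielding the dimensionless reference composition (the beta ratios)
#' against which a diet's own amino-acid-to-tryptophan ratios are judged.
#' The tryptophan ratio is exactly 1 by construction.
#'
#' @param pattern A requirement-pattern data frame with columns
#'   `amino_acid` and `level`, e.g. [hraap_default()].
#' @return A tibble with columns `amino_acid`, `code` and `beta`.
#' @export
#' @examples
#' beta_ratios(hraap_default())
beta_ratios <- function(pattern = hraap_default()) {
  pattern <- validate_pattern(pattern)
  trp_level <- pattern$level[pattern$code == "trp"]
  out <- pattern |>
    mutate(beta = .data$level / trp_level) |>
    select("amino_acid", "code", "beta")
  out$beta[out$code == "trp"] <- 1
  out
}
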
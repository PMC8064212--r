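#' Reference distribution of the 18 serum amino acids
#'
#' Per-amino-acid means and SDs (umol/L, typical fasting adult magnitudes)
#' and the default standardized slope on the dietary index used by the
#' generator. The sign structure follows the six amino acids consistently
#' associated with the index in both study cohorts: positive slopes for
#' valine, isoleucine, glutamic acid and phenylalanine; negative for
#' glycine and histidine; zero elsewhere.
#'
#' @return A tibble with columns `aa`, `mean`, `sd`, `beta`.
#' @export
serum_reference <- function() {
  tibble(
    aa = c("threonine", "glutamine", "arginine", "valine", "leucine",
           "isoleucine", "phenylalanine", "tryptophan", "serine",
           "methionine", "glycine", "proline", "histidine", "alanine",
           "lysine", "glutamic_acid", "aspartic_acid", "tyrosine"),
    mean = c(130, 550, 90, 230, 130, 65, 60, 55, 115, 25, 230, 180, 80,
             350, 180, 60, 10, 65),
    sd = c(30, 80, 25, 45, 30, 15, 12, 12, 25, 6, 60, 60, 12, 90, 40,
           25, 4, 15),
    beta = c(0, 0, 0, 0.13, 0, 0.13, 0.09, 0, 0, 0, -0.07, 0, -0.10, 0,
             0, 0.12, 0, 0)
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Bundles everything the generator needs: sample size, one global seed
#' (per-stage sub-seeds are derived deterministically from it), the
#' requirement pattern, how far intake composition departs from pattern
#' proportionality, covariate distributions, the serum model and the
#' outcome model. Defaults emulate the magnitudes of a middle-aged urban
#' Chinese cohort (mean energy ~2300 kcal/day, ~6-8% cumulative diabetes
#' incidence); they are emulation targets for testing, not estimates of any
#' real cohort.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param pattern Requirement-pattern table.
#' @param deviation_scale SD of the per-amino-acid lognormal multiplicative
#'   noise applied to pattern-proportional intakes; 0 gives an index of
#'   exactly 0 for every subject.
#' @param serum Serum model table as in [serum_reference()]; `beta` is the
#'   standardized slope of each serum amino acid on the index z-score.
#' @param outcome List with `link` (`"logit"`, the default, or
#'   `"probit"`), `intercept` (latent-scale intercept), `theta_exposure`
#'   (direct effect per SD of the index) and `theta_mediators` (named
#'   log-odds/probit effects per SD of each mediating serum amino acid,
#'   columns named `serum_<aa>`).
#' @return A list of class `aaci_sim_config`.
#' @export
sim_config <- function(n = 2000, seed = 1L, pattern = hraap_default(),
                       deviation_scale = 0.25,
                       serum = serum_reference(),
                       outcome = list(
                         link = "logit", intercept = -2.7,
                         theta_exposure = 0.25,
                         theta_mediators = c(serum_valine = 0.18,
                                             serum_glutamic_acid = 0.20,
                                             serum_histidine = -0.18)
                       )) {
  stopifnot(n >= 1, deviation_scale >= 0, all(serum$sd > 0))
  outcome$link <- outcome$link %||% "logit"
  stopifnot(outcome$link %in% c("logit", "probit"))
  structure(
    list(n = as.integer(n), seed = as.integer(seed), pattern = pattern,
         deviation_scale = deviation_scale, serum = serum,
         outcome = outcome),
    class = "aaci_sim_config"
  )
}

#' Calibrate a generator configuration to a target total percent mediated
#'
#' Under the generator's structural model — standardized mediators
#' `M_j = beta_j z + sqrt(1 - beta_j^2) e_j` with normal noise, and a
#' latent-index outcome `y* = b0 + theta_d z + sum theta_j M_j + eps` — the
#' population total percent mediated under y*-standardization is
#' `100 * sum(beta_j theta_j) / (theta_d + sum(beta_j theta_j))`, exactly
#' for the probit link (the normal mediator noise folds into the probit
#' error, so the marginal outcome model is again probit). Given a mediator
#' effect *shape*, the scale solving for the target percentage has the
#' closed form `s = (P/100) theta_d / ((1 - P/100) sum(beta_j u_j))`.
#'
#' @param target_total_percent Target total percent mediated.
#' @param n,seed Passed to [sim_config()].
#' @param theta_exposure Direct effect per SD of the index.
#' @param mediator_shape Named vector giving the relative sizes (and signs)
#'   of the mediator effects; names are `serum_<aa>` columns.
#' @param deviation_scale Passed to [sim_config()].
#' @param intercept Latent intercept controlling incidence.
#' @return An `aaci_sim_config` with a probit outcome whose implied total
#'   percent mediated equals the target; see [sim_ground_truth()].
#' @export
calibrate_mediation_sim <- function(target_total_percent = 30,
                                    n = 2000, seed = 1L,
                                    theta_exposure = 0.35,
                                    mediator_shape = c(
                                      serum_valine = 0.35,
                                      serum_glutamic_acid = 0.40,
                                      serum_histidine = -0.35
                                    ),
                                    deviation_scale = 0.25,
                                    intercept = -1.7) {
  serum <- serum_reference()
  aa <- sub("^serum_", "", names(mediator_shape))
  beta <- serum$beta[match(aa, serum$aa)]
  if (any(is.na(beta))) {
    abort("mediator_shape names must match serum_<aa> columns",
          class = "aaci_error_config")
  }
  share <- sum(beta * mediator_shape)
  if (share <= 0) {
    abort("mediator shape implies a non-positive mediated share; cannot calibrate",
          class = "aaci_error_config")
  }
  p <- target_total_percent / 100
  s <- p * theta_exposure / ((1 - p) * share)
  sim_config(
    n = n, seed = seed, deviation_scale = deviation_scale, serum = serum,
    outcome = list(
      link = "probit", intercept = intercept,
      theta_exposure = theta_exposure,
      theta_mediators = s * mediator_shape
    )
  )
}

#' Direct-effect size reproducing a given standardized total effect
#'
#' With no mediator effects, the y*-standardized total effect of a unit-SD
#' exposure is `theta / sqrt(theta^2 + c)` with `c` the latent error
#' variance of the link, so `theta = beta sqrt(c) / sqrt(1 - beta^2)`.
#'
#' @param beta_tot Target standardized total effect (|beta_tot| < 1).
#' @param link `"probit"` or `"logit"`.
#' @return The latent-scale exposure coefficient.
#' @export
calibrate_total_effect <- function(beta_tot, link = c("probit", "logit")) {
  link <- match.arg(link)
  stopifnot(abs(beta_tot) < 1)
  resvar <- if (link == "probit") 1 else pi^2 / 3
  beta_tot * sqrt(resvar) / sqrt(1 - beta_tot^2)
}

#' Population ground truth implied by a generator configuration
#'
#' Closed-form standardized paths, effects and percentages the analysis
#' stages target under the configuration's structural model (exact for the
#' probit link; for the logit link the marginal total-effect model is
#' approximated by rescaling the latent coefficient, the usual
#' normal-to-logistic folding approximation).
#'
#' @param config An `aaci_sim_config`.
#' @return A list: `a`, `b`, `direct`, `beta_tot`, `indirect`, `percent`,
#'   `percent_total`, and the serum slopes `serum_beta`.
#' @export
sim_ground_truth <- function(config) {
  oc <- config$outcome
  theta <- oc$theta_mediators
  aa <- sub("^serum_", "", names(theta))
  beta <- config$serum$beta[match(aa, config$serum$aa)]
  resvar <- if (oc$link == "probit") 1 else pi^2 / 3
  sigma2 <- 1 - beta^2
  c_lat <- oc$theta_exposure + sum(theta * beta)
  sd_yf <- sqrt(c_lat^2 + sum(theta^2 * sigma2) + resvar)
  a <- setNames(beta, names(theta))
  b <- theta / sd_yf
  indirect <- a * b
  beta_tot <- c_lat / sd_yf
  list(
    a = a, b = b, direct = oc$theta_exposure / sd_yf,
    beta_tot = beta_tot, indirect = indirect,
    percent = 100 * indirect / beta_tot,
    percent_total = 100 * sum(indirect) / beta_tot,
    serum_beta = setNames(config$serum$beta, config$serum$aa)
  )
}

simulate_covariates <- function(config) {
  n <- config$n
  withr::with_seed(stage_seed(config$seed, "covariates"), {
    tibble(
      subject_id = sprintf("s%05d", seq_len(n)),
      age = rnorm_trunc(n, 48, 10, 20, 74),
      sex = stats::rbinom(n, 1, 0.32),
      bmi = rnorm_trunc(n, 25, 3.5, 15, 45),
      education = stats::rbinom(n, 1, 0.70),
      smoking = stats::rbinom(n, 1, 0.15),
      drinking = stats::rbinom(n, 1, 0.33),
      exercise = stats::rbinom(n, 1, 0.50),
      energy_kcal = rnorm_trunc(n, 2300, 850, 500, 4500),
      protein_g = rnorm_trunc(n, 70, 25, 25, 200),
      fiber_g = rnorm_trunc(n, 14, 7, 1, 60),
      sfa_g = rnorm_trunc(n, 16, 8, 1, 80),
      diet_quality = rnorm_trunc(n, 50, 10, 10, 110),
      homa_ir = exp(rnorm(n, log(1.5), 0.5)),
      tc = rnorm_trunc(n, 5.0, 1.0, 2, 12),
      tg = exp(rnorm(n, log(1.6), 0.5)),
      hdl = rnorm_trunc(n, 1.28, 0.32, 0.4, 3),
      ldl = rnorm_trunc(n, 2.95, 0.9, 0.5, 8),
      t2dm_baseline = FALSE
    )
  })
}

#' Simulate per-subject amino-acid intakes
#'
#' Each subject's intake of amino acid *i* is
#' `protein_g x pattern_level_i x exp(e_i)` with
#' `e_i ~ Normal(0, deviation_scale^2)` independent across amino acids, so
#' the composition departs from pattern proportionality by a controllable
#' amount; `deviation_scale = 0` reproduces the pattern exactly and yields
#' an index of 0 for every subject.
#'
#' @param config An `aaci_sim_config`.
#' @param covariates Optional covariate tibble (from an earlier stage);
#'   generated if absent.
#' @return A tibble of intakes: `subject_id`, one column per amino-acid
#'   code (mg/day), and `energy_kcal`, `protein_g`, `fiber_g`, `sfa_g`.
#' @export
simulate_intakes <- function(config, covariates = NULL) {
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  n <- nrow(covariates)
  pat <- validate_pattern(config$pattern)
  codes <- unname(scored_amino_acids())
  levels <- setNames(pat$level, pat$code)[codes]
  withr::with_seed(stage_seed(config$seed, "intakes"), {
    eps <- matrix(rnorm(n * length(codes), 0, config$deviation_scale),
                  nrow = n, dimnames = list(NULL, codes))
    mat <- outer(covariates$protein_g, levels) * exp(eps)
    out <- tibble(subject_id = covariates$subject_id)
    out <- bind_cols(out, as_tibble(mat))
    out$energy_kcal <- covariates$energy_kcal
    out$protein_g <- covariates$protein_g
    out$fiber_g <- covariates$fiber_g
    out$sfa_g <- covariates$sfa_g
    out
  })
}

#' Simulate serum amino-acid profiles from the index
#'
#' Each serum amino acid is linear in the index z-score plus normal noise:
#' on the standardized scale `M = beta z + sqrt(1 - beta^2) e`, rescaled to
#' its reference mean and SD, so the injected `beta` is exactly the
#' population standardized slope recovered by a single-predictor model.
#'
#' @param aaci Numeric vector of index values.
#' @param config An `aaci_sim_config`.
#' @return A tibble with one `serum_<aa>` column per amino acid (umol/L).
#' @export
simulate_serum <- function(aaci, config) {
  n <- length(aaci)
  z <- if (!is_degenerate(aaci)) zscore(aaci) else rep(0, n)
  sr <- config$serum
  withr::with_seed(stage_seed(config$seed, "serum"), {
    cols <- purrr::pmap(sr, function(aa, mean, sd, beta) {
      mean + sd * (beta * z + sqrt(1 - beta^2) * rnorm(n))
    })
    out <- as_tibble(setNames(cols, paste0("serum_", sr$aa)))
    out
  })
}

#' Simulate diabetes incidence and consistent glycaemic measures
#'
#' Case probability follows the configured latent-index model
#' `P(case) = G(b0 + theta_d z(index) + sum theta_j z(serum_j))` with `G`
#' the logistic (default) or probit CDF. Fasting and 2-h glucose are then
#' drawn from case/non-case conditional distributions that straddle the
#' 7.0 / 11.1 mmol/L diagnostic thresholds, so [ascertain_t2dm()] applied
#' to the generated glucose reproduces the sampled flags exactly.
#'
#' @param data Cohort rows containing `aaci` and the mediating `serum_*`
#'   columns named in the configuration.
#' @param config An `aaci_sim_config`.
#' @return `data` with `t2dm`, `t2dm_self_report`, `t2dm_treatment`,
#'   `fasting_glucose`, `two_hour_glucose` and `hba1c` columns added.
#' @export
simulate_outcome <- function(data, config) {
  oc <- config$outcome
  n <- nrow(data)
  z <- if (!is_degenerate(data$aaci)) zscore(data$aaci) else rep(0, n)
  eta <- oc$intercept + oc$theta_exposure * z
  for (m in names(oc$theta_mediators)) {
    check_columns(data, m, "simulated cohort")
    eta <- eta + oc$theta_mediators[[m]] * zscore(data[[m]], m)
  }
  p <- if (oc$link == "probit") pnorm(eta) else plogis(eta)
  withr::with_seed(stage_seed(config$seed, "outcome"), {
    case <- stats::rbinom(n, 1, p) == 1
    inc <- mean(case)
    if (inc < 0.01 || inc > 0.5) {
      warn(sprintf("simulated incidence %.1f%% is outside the 1-50%% band",
                   100 * inc))
    }
    fasting <- ifelse(case,
                      rnorm_trunc(n, 8.0, 1.0, lower = 7.0),
                      rnorm_trunc(n, 4.6, 0.6, upper = 7.0 - 1e-6))
    two_hour <- ifelse(case,
                       rnorm_trunc(n, 10.5, 2.5, lower = 4.0),
                       rnorm_trunc(n, 5.7, 1.5, lower = 1.0,
                                   upper = 11.1 - 1e-6))
    data$t2dm <- case
    data$t2dm_self_report <- FALSE
    data$t2dm_treatment <- FALSE
    data$fasting_glucose <- fasting
    data$two_hour_glucose <- two_hour
    data$fasting_insulin <- exp(rnorm(n, log(8), 0.55))
    data$hba1c <- 2.9 + 0.45 * fasting + rnorm(n, 0, 0.3)
    as_tibble(data)
  })
}

#' Simulate a full cohort with known ground truth
#'
#' Runs the generator end to end — covariates, intakes, index, serum
#' profile, outcome — and returns the assembled cohort together with the
#' intake table and the population ground truth implied by the
#' configuration. Fixed seed gives a bit-identical dataset; each stage
#' draws from its own deterministically derived sub-stream, so stages can
#' be regenerated independently.
#'
#' @param config An `aaci_sim_config`.
#' @return A list of class `aaci_sim`: `cohort` (one row per subject with
#'   covariates, `aaci`, `tertile`, `serum_*`, glycaemic outcomes and the
#'   incident flag), `intakes`, `ground_truth`, `config`. When the index
#'   is degenerate (deviation_scale = 0) the tertile column is `NA` and
#'   association stages will refuse the exposure.
#' @export
simulate_cohort <- function(config = sim_config()) {
  covs <- simulate_covariates(config)
  intakes <- simulate_intakes(config, covs)
  idx <- compute_aaci(intakes, config$pattern)
  cohort <- bind_cols(covs, idx["aaci"])
  if (!is_degenerate(cohort$aaci) && length(unique(cohort$aaci)) >= 3) {
    cohort <- add_tertiles(cohort)
  } else {
    inform("degenerate index (all values equal); tertiles not assigned")
    cohort$tertile <- factor(rep(NA_character_, nrow(cohort)),
                             levels = c("T1", "T2", "T3"))
  }
  cohort <- bind_cols(cohort, simulate_serum(cohort$aaci, config))
  cohort <- simulate_outcome(cohort, config)
  structure(
    list(cohort = cohort, intakes = intakes,
         ground_truth = sim_ground_truth(config), config = config),
    class = "aaci_sim"
  )
}

#' Simulate FFQ records and a synthetic food-composition table
#'
#' Builds a 30-item, 13-group composition table whose amino-acid contents
#' are pattern-proportional to each item's protein content with mild
#' item-specific jitter — except rice items, which are deliberately poor in
#' lysine and threonine — and draws per-subject frequencies (lognormal) and
#' fixed portions. Raising `rice_weight` shifts consumption toward rice
#' and therefore away from pattern proportionality, raising the index on
#' average.
#'
#' @param config An `aaci_sim_config`.
#' @param rice_weight Multiplier on rice consumption frequency.
#' @return A list with `records` (long FFQ tibble) and `composition`
#'   (synthetic composition table; the table is labelled synthetic and is
#'   not derived from any published food-composition database).
#' @export
simulate_ffq <- function(config, rice_weight = 1) {
  pat <- validate_pattern(config$pattern)
  codes <- unname(scored_amino_acids())
  levels <- setNames(pat$level, pat$code)[codes]

  groups <- c(rice = 3, wheaten = 3, potato = 2, bean = 3, vegetable = 4,
              fruit = 3, livestock = 3, poultry = 2, dairy = 2, egg = 1,
              fish = 2, snack = 1, beverage = 1)
  protein100 <- c(rice = 7, wheaten = 10, potato = 2, bean = 20,
                  vegetable = 2, fruit = 1, livestock = 18, poultry = 19,
                  dairy = 3.3, egg = 13, fish = 18, snack = 8,
                  beverage = 0.5)
  energy100 <- c(rice = 350, wheaten = 340, potato = 80, bean = 330,
                 vegetable = 25, fruit = 50, livestock = 220, poultry = 160,
                 dairy = 60, egg = 145, fish = 110, snack = 450,
                 beverage = 40)
  base_freq <- c(rice = 2, wheaten = 1, potato = 0.4, bean = 0.5,
                 vegetable = 1.5, fruit = 0.8, livestock = 0.7,
                 poultry = 0.3, dairy = 0.6, egg = 0.8, fish = 0.4,
                 snack = 0.3, beverage = 0.4)
  portion <- c(rice = 150, wheaten = 100, potato = 100, bean = 50,
               vegetable = 150, fruit = 150, livestock = 75, poultry = 75,
               dairy = 200, egg = 50, fish = 75, snack = 40,
               beverage = 250)

  withr::with_seed(stage_seed(config$seed, "ffq"), {
    grp <- rep(names(groups), groups)
    n_items <- length(grp)
    comp <- tibble(
      food_id = sprintf("f%02d", seq_len(n_items)),
      food_group = grp,
      energy_kcal = energy100[grp] * exp(rnorm(n_items, 0, 0.1)),
      protein_g = protein100[grp] * exp(rnorm(n_items, 0, 0.1)),
      fiber_g = ifelse(grp %in% c("vegetable", "fruit", "bean"), 2.5, 0.8) *
        exp(rnorm(n_items, 0, 0.2)),
      sfa_g = ifelse(grp %in% c("livestock", "dairy", "snack"), 4, 0.5) *
        exp(rnorm(n_items, 0, 0.2))
    )
    aa_jitter <- matrix(exp(rnorm(n_items * length(codes), 0, 0.15)),
                        nrow = n_items, dimnames = list(NULL, codes))
    aa100 <- outer(comp$protein_g, levels) * aa_jitter
    # rice is deliberately lysine- and threonine-poor
    aa100[grp == "rice", "lys"] <- aa100[grp == "rice", "lys"] * 0.35
    aa100[grp == "rice", "thr"] <- aa100[grp == "rice", "thr"] * 0.50
    aa_tbl <- as_tibble(aa100)
    names(aa_tbl) <- paste0(codes, "_mg")
    comp <- bind_cols(comp, aa_tbl)

    n <- config$n
    records <- tidyr::expand_grid(
      subject_id = sprintf("s%05d", seq_len(n)),
      food_id = comp$food_id
    )
    g_of <- grp[match(records$food_id, comp$food_id)]
    freq <- base_freq[g_of] * exp(rnorm(nrow(records), 0, 0.6))
    freq[g_of == "rice"] <- freq[g_of == "rice"] * rice_weight
    records$frequency_per_day <- freq
    records$portion_g <- portion[g_of]
    list(records = records, composition = comp)
  })
}
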
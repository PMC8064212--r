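#' Specification of a parallel multiple-mediator analysis
#'
#' Describes the exposure, the parallel mediators (default: serum valine,
#' glutamic acid and histidine), the binary or continuous outcome, the
#' covariate adjustment set, the outcome link, and the bootstrap settings.
#'
#' The `link` controls how a binary outcome is placed on a standardized
#' scale: `"probit"` (default) and `"logit"` fit the corresponding
#' generalized linear model and standardize coefficients on the latent
#' index scale (y*-standardization: the latent scale's SD is
#' \eqn{\sqrt{\mathrm{var}(X\hat\beta) + c}} with \eqn{c = 1} for probit
#' and \eqn{\pi^2/3} for logit); `"linear"` treats the outcome as numeric
#' and standardizes by its sample SD, under which the effect decomposition
#' `total = direct + sum(indirect)` is exact.
#'
#' @param exposure Exposure column name.
#' @param mediators Character vector of mediator columns (parallel: all
#'   enter the outcome model jointly, with no mediator-to-mediator paths).
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (may be empty).
#' @param n_bootstrap Number of case-resampling bootstrap replicates
#'   (>= 1); `1` means no resampling (degenerate intervals at the point
#'   estimate).
#' @param seed Integer seed making the bootstrap deterministic.
#' @param link `"probit"`, `"logit"` or `"linear"`.
#' @return A list of class `aaci_mediation_spec`.
#' @export
mediation_spec <- function(exposure = "aaci",
                           mediators = c("serum_valine",
                                         "serum_glutamic_acid",
                                         "serum_histidine"),
                           outcome = "t2dm",
                           covariates = character(),
                           n_bootstrap = 1000, seed = 1L,
                           link = c("probit", "logit", "linear")) {
  link <- match.arg(link)
  overlap <- intersect(mediators, c(exposure, outcome, covariates))
  if (length(overlap) > 0) {
    abort(
      sprintf("mediators must be distinct from exposure/outcome/covariates: %s",
              paste(overlap, collapse = ", ")),
      class = "aaci_error_config"
    )
  }
  if (length(mediators) < 1 || anyDuplicated(mediators)) {
    abort("at least one mediator, all distinct, is required",
          class = "aaci_error_config")
  }
  if (!is.numeric(n_bootstrap) || n_bootstrap < 1) {
    abort("n_bootstrap must be >= 1", class = "aaci_error_config")
  }
  structure(
    list(exposure = exposure, mediators = mediators, outcome = outcome,
         covariates = covariates, n_bootstrap = as.integer(n_bootstrap),
         seed = as.integer(seed), link = link),
    class = "aaci_mediation_spec"
  )
}

# OLS on a prebuilt design, possibly with a multi-column response; returns
# raw coefficients, their standard errors and residual d.f.
ols_engine <- function(X, Y, want_se = TRUE) {
  Y <- as.matrix(Y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("rank-deficient design matrix in mediation fit",
          class = "aaci_error_fit")
  }
  coefs <- qr.coef(qx, Y)
  if (!want_se) {
    return(list(coef = coefs))
  }
  res <- Y - X %*% coefs
  df <- nrow(X) - qx$rank
  # diag of (X'X)^-1, mapped back from the QR's pivoted column order
  d_piv <- diag(chol2inv(qr.R(qx)))
  d <- numeric(ncol(X))
  d[qx$pivot] <- d_piv
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(d, sigma2))
  rownames(se) <- colnames(X)
  list(coef = coefs, se = se, df = df)
}

# binomial GLM on a prebuilt design via glm.fit; separation warnings are
# muffled inside the bootstrap, checked at the point estimate
glm_engine <- function(X, y, link, check = TRUE, want_se = TRUE) {
  fam <- binomial(link = link)
  fit <- suppressWarnings(glm.fit(X, y, family = fam))
  if (check && (!fit$converged || any(abs(fit$coefficients) > 25))) {
    abort("mediation outcome model did not converge (possible separation)",
          class = "aaci_error_fit")
  }
  se <- NULL
  if (want_se) {
    Qr <- fit$qr
    p1 <- seq_len(fit$rank)
    covmat <- chol2inv(Qr$qr[p1, p1, drop = FALSE])
    se <- rep(NA_real_, length(fit$coefficients))
    se[Qr$pivot[p1]] <- sqrt(diag(covmat))
    names(se) <- names(fit$coefficients)
  }
  list(
    coef = fit$coefficients,
    se = se,
    eta = fit$linear.predictors
  )
}

# point estimates of all standardized paths on prebuilt matrices.
# Xc: covariate design including intercept; x: exposure; M: mediator matrix
med_point <- function(x, M, y, Xc, link, with_se = FALSE) {
  Xa <- cbind(Xc, .x_ = x)
  Xf <- cbind(Xa, M)
  k <- ncol(M)
  sdx <- sd(x)
  sdm <- apply(M, 2, sd)

  afit <- ols_engine(Xa, M, want_se = with_se)
  a_raw <- afit$coef[".x_", ]

  if (link == "linear") {
    ffit <- ols_engine(Xf, y, want_se = with_se)
    tfit <- ols_engine(Xa, y, want_se = with_se)
    coef_f <- ffit$coef[, 1]
    coef_t <- tfit$coef[, 1]
    sdy_f <- sdy_t <- sd(y)
    if (with_se) {
      se_f <- ffit$se[, 1]
      se_t <- tfit$se[, 1]
    }
    pfun_out <- function(est, se, df) 2 * pt(-abs(est / se), df)
    df_f <- ffit$df
    df_t <- tfit$df
  } else {
    resvar <- if (link == "probit") 1 else pi^2 / 3
    ffit <- glm_engine(Xf, y, link, check = with_se, want_se = with_se)
    tfit <- glm_engine(Xa, y, link, check = with_se, want_se = with_se)
    coef_f <- ffit$coef
    coef_t <- tfit$coef
    # y*-standardization: latent-index SD of each model's own linear predictor
    sdy_f <- sqrt(var(ffit$eta) + resvar)
    sdy_t <- sqrt(var(tfit$eta) + resvar)
    if (with_se) {
      se_f <- ffit$se
      se_t <- tfit$se
    }
    pfun_out <- function(est, se, df) 2 * pnorm(-abs(est / se))
    df_f <- df_t <- Inf
  }

  med_names <- colnames(M)
  a <- a_raw * sdx / sdm
  b <- coef_f[med_names] * sdm / sdy_f
  direct <- coef_f[[".x_"]] * sdx / sdy_f
  beta_tot <- coef_t[[".x_"]] * sdx / sdy_t
  indirect <- a * b
  out <- list(
    a = a, b = b, indirect = indirect,
    direct = direct, beta_tot = beta_tot,
    indirect_total = sum(indirect)
  )
  if (abs(beta_tot) > 1e-12) {
    out$percent <- 100 * indirect / beta_tot
    out$percent_total <- sum(out$percent)
  } else {
    out$percent <- rep(NA_real_, k)
    out$percent_total <- NA_real_
  }
  if (with_se) {
    t_a <- a_raw / afit$se[".x_", ]
    out$a_p <- 2 * pt(-abs(t_a), afit$df)
    out$b_p <- pfun_out(coef_f[med_names], se_f[med_names], df_f)
    out$direct_p <- pfun_out(coef_f[[".x_"]], se_f[[".x_"]], df_f)
    out$beta_tot_p <- pfun_out(coef_t[[".x_"]], se_t[[".x_"]], df_t)
  }
  out
}

med_stat_vector <- function(p) {
  k <- length(p$a)
  nm <- names(p$a)
  c(
    setNames(p$a, paste0("a_", nm)),
    setNames(p$b, paste0("b_", nm)),
    setNames(p$indirect, paste0("indirect_", nm)),
    setNames(p$percent, paste0("percent_", nm)),
    direct = p$direct, beta_tot = p$beta_tot,
    indirect_total = p$indirect_total, percent_total = p$percent_total
  )
}

#' Parallel multiple-mediator decomposition with bootstrap intervals
#'
#' Decomposes the covariate-adjusted association between an exposure and an
#' outcome into a direct effect and per-mediator indirect effects using the
#' product-of-coefficients method in a parallel-mediator model:
#'
#' * the total effect `beta_tot` is the standardized exposure coefficient
#'   in the outcome model *without* mediators;
#' * each a-path is the standardized exposure coefficient in a
#'   covariate-adjusted linear model of that mediator;
#' * each b-path is the standardized coefficient of that mediator in the
#'   outcome model containing the exposure and *all* mediators jointly,
#'   whose exposure coefficient is the direct effect;
#' * each indirect effect is `a x b`, and the percent mediated is
#'   `100 * a * b / beta_tot`; the total percent mediated is their signed
#'   sum, so inconsistent (suppression) mediation yields negative
#'   components.
#'
#' Confidence intervals for every path, indirect effect and percentage are
#' percentile intervals from a case-resampling bootstrap, deterministic
#' given the spec's seed. Bootstrap replicates in which the resampled
#' binary outcome has no cases (or no non-cases) are dropped and counted; a
#' warning is issued if more than 10% are dropped.
#'
#' @param data Cohort data frame; rows with missing analysis variables are
#'   removed listwise.
#' @param spec A [mediation_spec()].
#' @return An object of class `aaci_mediation` with elements `paths` (one
#'   tibble row per mediator: a, b, indirect, percent, p-values,
#'   percentile CIs), `effects` (total, direct, total indirect, total
#'   percent with CIs), `spec`, `n`, `n_boot_used`, `n_boot_dropped`.
#'   Supports [tidy()], [glance()], `print()` and [autoplot()].
#' @export
mediate_aaci <- function(data, spec = mediation_spec()) {
  stopifnot(inherits(spec, "aaci_mediation_spec"))
  vars <- c(spec$exposure, spec$mediators, spec$outcome, spec$covariates)
  check_columns(data, vars, "cohort table")
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < length(vars) + 2) {
    abort("too few complete cases for the mediation model",
          class = "aaci_error_degenerate")
  }

  x <- as.numeric(d[[spec$exposure]])
  M <- as.matrix(d[spec$mediators])
  y <- as.numeric(d[[spec$outcome]])
  if (spec$link != "linear" && !all(y %in% c(0, 1))) {
    abort("binary-link mediation requires a 0/1 outcome",
          class = "aaci_error_domain")
  }
  Xc <- if (length(spec$covariates) > 0) {
    model.matrix(~ ., data = d[spec$covariates])
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  if (ncol(M) > 1) {
    cn <- kappa(stats::cor(M), exact = TRUE)
    if (cn > 1e4) {
      warn(sprintf(
        "mediators are nearly collinear (condition number %.3g); paths may be unstable",
        cn
      ))
    }
  }

  point <- med_point(x, M, y, Xc, spec$link, with_se = TRUE)
  stat_point <- med_stat_vector(point)

  n_dropped <- 0L
  if (spec$n_bootstrap == 1) {
    # no resampling: degenerate intervals at the point estimate
    lo <- hi <- stat_point
    n_used <- 1L
  } else {
    binary <- spec$link != "linear" || all(y %in% c(0, 1))
    draws <- withr::with_seed(stage_seed(spec$seed, "bootstrap"), {
      purrr::map(seq_len(spec$n_bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (binary && (sum(yb) == 0 || sum(yb) == n)) {
          return(NULL)
        }
        pb <- tryCatch(
          med_point(x[idx], M[idx, , drop = FALSE], yb,
                    Xc[idx, , drop = FALSE], spec$link),
          error = function(e) NULL
        )
        if (is.null(pb)) NULL else med_stat_vector(pb)
      })
    })
    ok <- !vapply(draws, is.null, logical(1))
    n_dropped <- sum(!ok)
    if (n_dropped > 0.1 * spec$n_bootstrap) {
      warn(sprintf("%d of %d bootstrap replicates dropped (degenerate resample)",
                   n_dropped, spec$n_bootstrap))
    }
    boot <- do.call(rbind, draws[ok])
    lo <- apply(boot, 2, quantile, probs = 0.025, na.rm = TRUE, type = 7)
    hi <- apply(boot, 2, quantile, probs = 0.975, na.rm = TRUE, type = 7)
    n_used <- sum(ok)
  }

  km <- spec$mediators
  grab <- function(prefix, v) unname(v[paste0(prefix, km)])
  paths <- tibble(
    mediator = km,
    a = unname(point$a), a_p = unname(point$a_p),
    a_low = grab("a_", lo), a_high = grab("a_", hi),
    b = unname(point$b), b_p = unname(point$b_p),
    b_low = grab("b_", lo), b_high = grab("b_", hi),
    indirect = unname(point$indirect),
    indirect_low = grab("indirect_", lo), indirect_high = grab("indirect_", hi),
    percent = unname(point$percent),
    percent_low = grab("percent_", lo), percent_high = grab("percent_", hi)
  )
  eff_names <- c("beta_tot", "direct", "indirect_total", "percent_total")
  effects <- tibble(
    term = c("total", "direct", "indirect_total", "percent_total"),
    estimate = unname(stat_point[eff_names]),
    conf_low = unname(lo[eff_names]),
    conf_high = unname(hi[eff_names]),
    p_value = c(point$beta_tot_p, point$direct_p, NA_real_, NA_real_)
  )
  if (is.na(point$percent_total)) {
    warn("total effect is numerically zero; percent mediated is undefined (NA)")
  } else if (sign(point$indirect_total) != sign(point$beta_tot) &&
             point$indirect_total != 0) {
    inform("indirect and total effects have opposite signs (inconsistent mediation); percentages are reported signed")
  }

  structure(
    list(paths = paths, effects = effects, spec = spec, n = n,
         n_boot_used = if (spec$n_bootstrap == 1) 1L else n_used,
         n_boot_dropped = n_dropped),
    class = "aaci_mediation"
  )
}

#' Per-mediator and total percent mediated
#'
#' The share of the total effect transmitted through each mediator,
#' `100 * indirect / total`, and their signed sum. Undefined (all `NA`,
#' with a warning) when the total effect is numerically zero.
#'
#' @param indirect Named or unnamed numeric vector of indirect effects
#'   (products a x b), on the same standardized scale as `total_effect`.
#' @param total_effect The standardized total effect.
#' @return A tibble with one row per mediator plus a `"total"` row.
#' @export
#' @examples
#' percent_mediated(c(valine = 0.12, histidine = -0.03), total_effect = 0.5)
percent_mediated <- function(indirect, total_effect) {
  nm <- names(indirect) %||% paste0("mediator", seq_along(indirect))
  if (!is.finite(total_effect) || abs(total_effect) < 1e-12) {
    warn("total effect is numerically zero; percent mediated is undefined")
    pct <- rep(NA_real_, length(indirect))
  } else {
    pct <- 100 * indirect / total_effect
  }
  tibble(
    mediator = c(nm, "total"),
    percent = unname(c(pct, sum(pct)))
  )
}

#' @method tidy aaci_mediation
#' @export
tidy.aaci_mediation <- function(x, ...) {
  x$paths
}

#' @method glance aaci_mediation
#' @export
glance.aaci_mediation <- function(x, ...) {
  e <- setNames(x$effects$estimate, x$effects$term)
  tibble(
    beta_tot = e[["total"]], direct = e[["direct"]],
    indirect_total = e[["indirect_total"]],
    percent_total = e[["percent_total"]],
    n = x$n, n_boot = x$n_boot_used, link = x$spec$link
  )
}

#' @method print aaci_mediation
#' @export
print.aaci_mediation <- function(x, ...) {
  s <- x$spec
  e <- setNames(x$effects$estimate, x$effects$term)
  cat(sprintf("Parallel mediation: %s -> {%s} -> %s (%s link, n = %d)\n",
              s$exposure, paste(s$mediators, collapse = ", "), s$outcome,
              s$link, x$n))
  cat(sprintf("  total effect  %7.3f   direct %7.3f   indirect %7.3f\n",
              e[["total"]], e[["direct"]], e[["indirect_total"]]))
  for (i in seq_len(nrow(x$paths))) {
    p <- x$paths[i, ]
    cat(sprintf("  %s -(a=%.3f)-> %s -(b=%.3f)-> %s : indirect %.3f (%.1f%% mediated)\n",
                s$exposure, p$a, p$mediator, p$b, s$outcome, p$indirect,
                p$percent))
  }
  if (!is.na(e[["percent_total"]])) {
    cat(sprintf("  total percent mediated: %.1f%% [%.1f, %.1f] (%d bootstrap replicates)\n",
                e[["percent_total"]],
                x$effects$conf_low[x$effects$term == "percent_total"],
                x$effects$conf_high[x$effects$term == "percent_total"],
                x$n_boot_used))
  }
  invisible(x)
}
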
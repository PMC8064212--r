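# independent oracles and fixture builders shared across tests

# scalar-loop re-implementation of the index: explicit per-subject,
# per-amino-acid arithmetic, no vectorization, no shared code path
scalar_aaci <- function(intake, pattern = hraap_default()) {
  codes <- unname(scored_amino_acids())
  lev <- setNames(pattern$level, canonical_names_to_codes(pattern$amino_acid))
  beta_trp <- lev[["trp"]]
  out <- numeric(nrow(intake))
  for (i in seq_len(nrow(intake))) {
    total <- 0
    trp_int <- intake[["trp"]][i]
    for (code in codes) {
      beta <- lev[[code]] / beta_trp
      ratio <- intake[[code]][i] / trp_int
      q <- abs(ratio * (1 / beta) - 1)
      if (code == "trp") q <- 0
      total <- total + q
    }
    out[i] <- total
  }
  out
}

canonical_names_to_codes <- function(x) {
  vocab <- scored_amino_acids()
  ifelse(tolower(x) %in% vocab, tolower(x), vocab[tolower(x)])
}

# hand-rolled iteratively reweighted least squares for logistic regression,
# independent of stats::glm
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

# random intake profiles with lognormal deviations around the pattern
random_intakes <- function(n, seed, deviation = 0.4) {
  pattern <- hraap_default()
  codes <- unname(scored_amino_acids())
  lev <- setNames(pattern$level, canonical_names_to_codes(pattern$amino_acid))
  withr::with_seed(seed, {
    scale <- exp(rnorm(n, log(60), 0.3))
    mat <- outer(scale, lev[codes]) *
      matrix(exp(rnorm(n * length(codes), 0, deviation)), nrow = n)
    out <- tibble::tibble(subject_id = sprintf("r%04d", seq_len(n)))
    dplyr::bind_cols(out, tibble::as_tibble(mat))
  })
}

# tiny hand-checkable food fixtures
toy_composition <- function() {
  codes <- unname(scored_amino_acids())
  base <- tibble::tibble(
    food_id = c("rice", "egg", "milk"),
    food_group = c("rice", "egg", "dairy"),
    energy_kcal = c(350, 145, 60),
    protein_g = c(7, 13, 3.3),
    fiber_g = c(0.4, 0, 0),
    sfa_g = c(0.2, 3.1, 1.1)
  )
  aa <- matrix(0, nrow = 3, ncol = length(codes),
               dimnames = list(NULL, paste0(codes, "_mg")))
  aa[, "val_mg"] <- c(250, 800, 180)
  aa[, "trp_mg"] <- c(80, 170, 40)
  aa[, "lys_mg"] <- c(120, 900, 220)
  aa[, "thr_mg"] <- c(150, 600, 120)
  dplyr::bind_cols(base, tibble::as_tibble(aa))
}
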
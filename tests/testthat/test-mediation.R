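make_linear_chain <- function(n, seed, a = 0.4, b = 0.3, direct = 0.2,
                              noise_m = 1, noise_y = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + rnorm(n, 0, noise_m)
    y <- direct * x + b * m + rnorm(n, 0, noise_y)
    tibble::tibble(x = x, m = m, y = y)
  })
}

test_that("linear-link decomposition is exact: total = direct + sum(indirect)", {
  for (seed in c(1, 7, 23)) {
    sim <- simulate_cohort(sim_config(n = 400, seed = seed))
    co <- sim$cohort
    co$y_cont <- as.numeric(co$t2dm) # any numeric outcome works
    med <- mediate_aaci(co, mediation_spec(
      outcome = "y_cont", covariates = c("age", "sex", "bmi"),
      n_bootstrap = 1, link = "linear"
    ))
    e <- setNames(med$effects$estimate, med$effects$term)
    expect_lt(abs(e[["total"]] - e[["direct"]] - e[["indirect_total"]]), 1e-8)
    # percentages sum exactly to the reported total
    expect_equal(sum(med$paths$percent), e[["percent_total"]])
  }
})

test_that("a single linear chain recovers its injected product of coefficients", {
  d <- make_linear_chain(20000, seed = 5)
  med <- mediate_aaci(d, mediation_spec(
    exposure = "x", mediators = "m", outcome = "y",
    n_bootstrap = 1, link = "linear"
  ))
  p <- med$paths
  # standardized truth: a* = 0.4/sd(m); b* = 0.3 sd(m)/sd(y)
  a_true <- 0.4 / sqrt(0.4^2 + 1)
  sd_y <- sqrt(0.2^2 + 0.3^2 * (0.4^2 + 1) + 2 * 0.2 * 0.3 * 0.4 + 1)
  expect_lt(abs(p$a - a_true), 0.02)
  expect_lt(abs(p$indirect - 0.4 * 0.3 / sd_y), 0.01)

  # noiseless chain: the product is recovered exactly
  d0 <- make_linear_chain(500, seed = 9, noise_m = 1, noise_y = 0)
  med0 <- mediate_aaci(d0, mediation_spec(
    exposure = "x", mediators = "m", outcome = "y",
    n_bootstrap = 1, link = "linear"
  ))
  e0 <- setNames(med0$effects$estimate, med0$effects$term)
  expect_lt(abs(e0[["total"]] - e0[["direct"]] - e0[["indirect_total"]]),
            1e-10)
  expect_equal(med0$paths$b, 0.3 * sd(d0$m) / sd(d0$y), tolerance = 1e-8)
})

test_that("a mediator independent of the exposure carries no indirect effect", {
  withr::with_seed(44, {
    n <- 8000
    d <- tibble::tibble(
      x = rnorm(n),
      m = rnorm(n), # no a-path
      y = 0.3 * rnorm(n) + 0.25 * x
    )
  })
  med <- mediate_aaci(d, mediation_spec(
    exposure = "x", mediators = "m", outcome = "y",
    n_bootstrap = 1, link = "linear"
  ))
  expect_lt(abs(med$paths$a), 0.03)
  expect_lt(abs(med$paths$indirect), 0.01)
})

test_that("percent mediated aggregates by signed summation", {
  # three components and their signed total
  pm <- percent_mediated(c(v = 0.105, g = 0.133, h = 0.096) * 0.512,
                         total_effect = 0.512)
  expect_equal(pm$percent, c(10.5, 13.3, 9.6, 33.4))

  # suppression: a negative component reduces the total
  pm2 <- percent_mediated(c(a = 0.2, b = -0.05), total_effect = 0.5)
  expect_equal(pm2$percent[3], 100 * (0.2 - 0.05) / 0.5)

  expect_warning(percent_mediated(c(a = 0.1), total_effect = 0),
                 "undefined")
})

test_that("bootstrap is deterministic given the seed and degenerate at B = 1", {
  sim <- simulate_cohort(sim_config(n = 600, seed = 2))
  spec <- mediation_spec(covariates = c("age", "sex"), n_bootstrap = 60,
                         seed = 42, link = "probit")
  m1 <- mediate_aaci(sim$cohort, spec)
  m2 <- mediate_aaci(sim$cohort, spec)
  expect_identical(m1$paths, m2$paths)
  expect_identical(m1$effects, m2$effects)

  m3 <- mediate_aaci(sim$cohort, mediation_spec(
    covariates = c("age", "sex"), n_bootstrap = 60, seed = 43,
    link = "probit"
  ))
  expect_false(identical(m1$paths$indirect_low, m3$paths$indirect_low))

  m0 <- mediate_aaci(sim$cohort, mediation_spec(
    covariates = c("age", "sex"), n_bootstrap = 1, link = "probit"
  ))
  expect_equal(m0$paths$indirect_low, m0$paths$indirect)
  expect_equal(m0$paths$indirect_high, m0$paths$indirect)
})

test_that("probit ground truth is recovered on a large calibrated cohort", {
  cfg <- calibrate_mediation_sim(30, n = 20000, seed = 321)
  gt <- sim_ground_truth(cfg)
  expect_equal(gt$percent_total, 30, tolerance = 1e-10)
  sim <- simulate_cohort(cfg)
  med <- mediate_aaci(sim$cohort, mediation_spec(
    n_bootstrap = 1, link = "probit"
  ))
  e <- setNames(med$effects$estimate, med$effects$term)
  expect_lt(abs(e[["total"]] - gt$beta_tot), 0.03)
  expect_lt(abs(e[["percent_total"]] - 30), 5)
  expect_lt(max(abs(med$paths$a - gt$a)), 0.03)
  expect_lt(max(abs(med$paths$b - gt$b)), 0.03)
})

test_that("misconfigured mediation specs are refused", {
  expect_error(mediation_spec(mediators = c("aaci", "serum_valine")),
               class = "aaci_error_config")
  expect_error(mediation_spec(n_bootstrap = 0), class = "aaci_error_config")
  sim <- simulate_cohort(sim_config(n = 200, seed = 3))
  co <- sim$cohort
  withr::with_seed(1, {
    co$dup <- co$serum_valine + rnorm(nrow(co), 0, 1e-4) # near-collinear pair
  })
  expect_warning(
    mediate_aaci(co, mediation_spec(
      mediators = c("serum_valine", "dup"), n_bootstrap = 1, link = "linear",
      outcome = "bmi"
    )),
    "collinear"
  )
})
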
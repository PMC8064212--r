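test_that("case ascertainment honours the diagnostic thresholds inclusively", {
  d <- tibble::tibble(
    fasting_glucose = c(7.0, 5.1, 5.0, 6.999, NA, NA),
    two_hour_glucose = c(6.0, 11.1, 7.0, 11.099, NA, NA),
    t2dm_self_report = c(FALSE, FALSE, FALSE, FALSE, TRUE, NA),
    t2dm_treatment = c(FALSE, FALSE, FALSE, FALSE, FALSE, NA)
  )
  flags <- ascertain_t2dm(d)$t2dm
  expect_identical(flags, c(TRUE, TRUE, FALSE, FALSE, TRUE, NA))
})

test_that("raising glucose never converts a case to a non-case", {
  withr::with_seed(77, {
    d <- tibble::tibble(
      fasting_glucose = runif(300, 3, 9),
      two_hour_glucose = runif(300, 3, 13)
    )
  })
  base <- ascertain_t2dm(d)$t2dm
  bumped <- ascertain_t2dm(dplyr::mutate(
    d, fasting_glucose = fasting_glucose + 1.5
  ))$t2dm
  expect_true(all(bumped >= base))
})

test_that("baseline table matches a direct re-computation and flags injected shifts", {
  sim <- simulate_cohort(sim_config(n = 1200, seed = 4))
  co <- sim$cohort
  # inject a strong mean shift into one column and a balanced flag
  co$shifted <- rnorm(nrow(co)) + 2 * (as.integer(co$tertile) - 1)
  tab <- baseline_table(co, vars = c("age", "bmi", "smoking", "shifted"))

  ages <- tab[tab$variable == "age", ]
  for (tt in c("T1", "T2", "T3")) {
    x <- co$age[co$tertile == tt]
    expect_equal(ages$mean[ages$category == tt], mean(x))
    expect_equal(ages$sd[ages$category == tt], sd(x))
    expect_equal(ages$n[ages$category == tt], length(x))
  }
  expect_lt(tab$p_value[tab$variable == "shifted"][1], 0.001)

  # a flag with identical proportions across tertiles gives chi-square p ~ 1
  co$flat <- stats::ave(seq_len(nrow(co)), co$tertile, FUN = seq_along) %% 2 == 0
  tab2 <- baseline_table(co, vars = "flat")
  expect_gt(tab2$p_value[1], 0.99)
  expect_equal(tab2$pct[tab2$category == "T1"],
               100 * mean(co$flat[co$tertile == "T1"]))

  expect_error(
    baseline_table(dplyr::mutate(co, tertile = factor("T1", levels = c("T1", "T2")))),
    class = "aaci_error_degenerate"
  )
})

test_that("tertile logistic model agrees with a hand-rolled IRLS fit", {
  sim <- simulate_cohort(sim_config(n = 200, seed = 12))
  co <- sim$cohort
  fit <- fit_tertile_logistic(co, ladder = list(model1 = c("age", "sex")),
                              models = "model1")
  X <- cbind(1, co$tertile == "T2", co$tertile == "T3", co$age, co$sex)
  ref <- irls_logistic(X, as.integer(co$t2dm))
  got <- log(c(tidy(fit)$estimate[2:3]))
  expect_lt(max(abs(got - ref[2:3])), 1e-6)
})

test_that("null and monotone tertile risks are recovered", {
  withr::with_seed(501, {
    n <- 5000
    score <- sample(1:3, n, replace = TRUE)
    d_null <- tibble::tibble(
      t2dm = rbinom(n, 1, 0.08) == 1,
      tertile = factor(paste0("T", score)),
      age = rnorm(n, 48, 10), sex = rbinom(n, 1, 0.4)
    )
    d_mono <- d_null
    d_mono$t2dm <- rbinom(n, 1, plogis(-2.9 + 0.4 * (score - 1))) == 1
  })
  lad <- list(model1 = c("age", "sex"))
  f_null <- fit_tertile_logistic(d_null, ladder = lad, models = "model1")
  expect_lt(max(abs(log(tidy(f_null)$estimate[2:3]))), 0.25)
  expect_equal(tidy(f_null)$estimate[1], 1) # reference category exactly 1

  f_mono <- fit_tertile_logistic(d_mono, ladder = lad, models = "model1")
  expect_lt(abs(log(tidy(f_mono)$estimate[3]) - 0.8), 0.2)
  expect_lt(glance(f_mono)$p_trend, 0.05)
  # ordinal-score coefficient approaches the injected per-tertile slope
  expect_lt(abs(glance(f_mono)$trend_coef - 0.4), 0.1)
})

test_that("categories without cases are reported non-estimable, not crashed", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      tertile = factor(rep(c("T1", "T2", "T3"), each = 120)),
      t2dm = c(rbinom(120, 1, 0.2) == 1, rep(FALSE, 120),
               rbinom(120, 1, 0.25) == 1),
      age = rnorm(360, 50, 8), sex = rbinom(360, 1, 0.5)
    )
  })
  fit <- fit_tertile_logistic(d, ladder = list(m = c("age", "sex")),
                              models = "m")
  td <- tidy(fit)
  expect_equal(td$note[td$category == "T2"], "non-estimable")
  expect_true(is.na(td$estimate[td$category == "T2"]))
  expect_false(is.na(td$estimate[td$category == "T3"]))
})

test_that("standardized linear betas behave as an effect-size scale", {
  sim <- simulate_cohort(sim_config(n = 4000, seed = 33))
  co <- sim$cohort
  lad <- list(m1 = c("age", "sex"))

  # identity: regressing the exposure on itself gives beta 1
  co$self <- co$aaci
  expect_equal(
    suppressWarnings(fit_linear_std(co, "self", ladder = lad,
                                    models = "m1")$beta), 1,
    tolerance = 1e-8
  )

  # null outcome: beta near 0
  withr::with_seed(2, co$noise <- rnorm(nrow(co)))
  expect_lt(abs(fit_linear_std(co, "noise", ladder = lad,
                               models = "m1")$beta), 0.04)

  # recovery: outcome = 0.1 z(exposure) + noise
  withr::with_seed(3, {
    co$dep <- 0.1 * scale(co$aaci)[, 1] + rnorm(nrow(co))
  })
  row <- fit_linear_std(co, "dep", ladder = lad, models = "m1")
  expect_lt(abs(row$beta - 0.1 / sd(co$dep)), 2 * row$se)

  # affine rescaling of exposure and outcome leaves beta unchanged
  co2 <- co
  co2$aaci <- 100 * co2$aaci + 7
  co2$dep <- 0.001 * co2$dep - 5
  expect_equal(
    fit_linear_std(co2, "dep", ladder = lad, models = "m1")$beta,
    row$beta, tolerance = 1e-10
  )
})

test_that("injected serum slopes propagate to standardized betas with sign", {
  sim <- simulate_cohort(sim_config(n = 6000, seed = 19))
  co <- sim$cohort
  res <- fit_linear_std(
    co, c("serum_valine", "serum_histidine", "serum_threonine"),
    ladder = list(m1 = c("age", "sex")), models = "m1"
  )
  truth <- sim$ground_truth$serum_beta
  expect_gt(res$beta[res$outcome == "serum_valine"], 0.08) # injected +0.13
  expect_lt(res$beta[res$outcome == "serum_histidine"], -0.05) # injected -0.10
  expect_lt(abs(res$beta[res$outcome == "serum_threonine"]), 0.04) # null
  expect_lt(abs(res$beta[res$outcome == "serum_valine"] - truth[["valine"]]),
            2.5 * res$se[res$outcome == "serum_valine"])
})

test_that("serum quartile models use Q1 as reference and recover direction", {
  withr::with_seed(91, {
    n <- 6000
    m <- rnorm(n)
    q <- cut(m, quantile(m, c(0, .25, .5, .75, 1)), include.lowest = TRUE,
             labels = FALSE)
    d <- tibble::tibble(
      serum_histidine = m,
      t2dm = rbinom(n, 1, plogis(-2.2 - 0.3 * (q - 1))) == 1,
      age = rnorm(n, 50, 9), sex = rbinom(n, 1, 0.4)
    )
  })
  fit <- serum_quartile_logistic(d, "histidine", covariates = c("age", "sex"))
  td <- tidy(fit)
  expect_equal(td$estimate[1], 1)
  expect_equal(td$category, paste0("Q", 1:4))
  expect_lt(td$estimate[4], td$estimate[2]) # protective gradient
  expect_lt(td$estimate[4], 0.7)
  expect_lt(glance(fit)$p_trend, 0.001)
})

test_that("food-group correlations detect construction and ties behave", {
  sim <- simulate_cohort(sim_config(n = 800, seed = 14))
  co <- sim$cohort
  withr::with_seed(6, {
    groups <- tibble::tibble(
      subject_id = co$subject_id,
      rice = 100 + 40 * scale(co$aaci)[, 1] + rnorm(nrow(co), 0, 10),
      exact = co$aaci,
      flat = 50
    )
  })
  res <- food_group_trend(co, groups)
  expect_gt(res$rho[res$food_group == "rice"], 0.5)
  expect_lt(res$p_value[res$food_group == "rice"], 0.001)
  expect_equal(res$rho[res$food_group == "exact"], 1)
  expect_true(is.na(res$rho[res$food_group == "flat"]))

  # permuted intake should decorrelate
  withr::with_seed(7, groups$rice <- sample(groups$rice))
  res2 <- food_group_trend(co, groups)
  expect_lt(abs(res2$rho[res2$food_group == "rice"]), 0.1)
})
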
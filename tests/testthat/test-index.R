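test_that("reference ratios divide each requirement level by tryptophan's", {
  br <- beta_ratios(hraap_default())
  expect_equal(br$beta[br$code == "trp"], 1)
  expect_equal(br$beta[br$code == "his"], 15 / 6) # 2.5
  expect_equal(br$beta[br$code == "val"], 39 / 6) # 6.5
  expect_true(all(br$beta > 0))

  flat <- hraap_default()
  flat$level <- 6
  expect_equal(beta_ratios(flat)$beta, rep(1, 11))
})

test_that("invalid patterns are rejected with the offending amino acid named", {
  no_trp <- hraap_default()[hraap_default()$amino_acid != "tryptophan", ]
  expect_error(beta_ratios(no_trp), "trp", class = "aaci_error_config")

  neg <- hraap_default()
  neg$level[neg$amino_acid == "lysine"] <- -1
  expect_error(beta_ratios(neg), "lysine", class = "aaci_error_config")
})

test_that("satisfaction scores follow the absolute-relative-deviation formula", {
  # one subject engineered so valine has intake/trp = 5 against beta 2.5 (q=1)
  # and histidine intake/trp = 1.25 against beta 2.5 (q=0.5); all other amino
  # acids proportional to the pattern
  pattern <- hraap_default()
  lev <- setNames(pattern$level, canonical_names_to_codes(pattern$amino_acid))
  codes <- unname(scored_amino_acids())
  intake <- tibble::as_tibble(as.list(setNames(100 * lev[codes], codes)))
  intake$subject_id <- "s1"
  pat <- hraap_default()
  pat$level[pat$amino_acid == "valine"] <- 15 # beta_val = 15/6 = 2.5
  intake$val <- 5 * intake$trp
  intake$his <- 1.25 * intake$trp # beta_his = 2.5
  res <- compute_aaci(intake, pat)
  expect_equal(res$q_val, abs(5 / 2.5 - 1)) # 1.0
  expect_equal(res$q_his, abs(1.25 / 2.5 - 1)) # 0.5, deficiency also positive
  expect_equal(res$q_trp, 0)
  # remaining terms vanish except the two engineered ones: aaci = 1.5
  expect_equal(res$aaci, 1.5)
})

test_that("proportional diets score zero and the index is scale invariant", {
  pattern <- hraap_default()
  lev <- setNames(pattern$level, canonical_names_to_codes(pattern$amino_acid))
  codes <- unname(scored_amino_acids())
  withr::with_seed(42, {
    for (k in c(0.3, 1, 57.2)) {
      intake <- tibble::as_tibble(as.list(setNames(k * lev[codes], codes)))
      intake$subject_id <- "p"
      expect_equal(compute_aaci(intake, pattern)$aaci, 0)
    }
  })
  profiles <- random_intakes(50, seed = 9)
  base <- compute_aaci(profiles)$aaci
  for (c_scale in c(0.01, 3.7, 1000)) {
    scaled <- profiles
    scaled[unname(scored_amino_acids())] <-
      scaled[unname(scored_amino_acids())] * c_scale
    expect_equal(compute_aaci(scaled)$aaci, base, tolerance = 1e-12)
  }
})

test_that("moving one amino acid away from proportionality raises its score", {
  pattern <- hraap_default()
  lev <- setNames(pattern$level, canonical_names_to_codes(pattern$amino_acid))
  codes <- unname(scored_amino_acids())
  intake <- tibble::as_tibble(as.list(setNames(10 * lev[codes], codes)))
  intake$subject_id <- "m"
  at <- function(mult) {
    d <- intake
    d$leu <- d$leu * mult
    compute_aaci(d, pattern)$q_leu
  }
  up <- vapply(c(1, 1.2, 1.8, 3), at, numeric(1))
  down <- vapply(c(1, 0.8, 0.4, 0.1), at, numeric(1))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) > 0))
})

test_that("vectorized index matches the scalar-loop oracle", {
  profiles <- random_intakes(250, seed = 31)
  expect_lt(
    max(abs(compute_aaci(profiles)$aaci - scalar_aaci(profiles))),
    1e-12
  )
})

test_that("tryptophan intake must be strictly positive", {
  profiles <- random_intakes(3, seed = 1)
  profiles$trp[2] <- 0
  expect_error(compute_aaci(profiles), "r0002", class = "aaci_error_domain")
})

test_that("tertiles split at the empirical cutpoints with closed upper bounds", {
  t <- aaci_tertiles(1:9)
  expect_equal(as.character(t),
               c("T1", "T1", "T1", "T2", "T2", "T2", "T3", "T3", "T3"))
  expect_length(attr(t, "cutpoints"), 2)

  # explicit published-style cutpoints: 3.40 falls in the middle band
  t2 <- aaci_tertiles(c(3.40, 3.20, 3.60), cutpoints = c(3.32, 3.57))
  expect_equal(as.character(t2), c("T2", "T1", "T3"))
  # a value tied with a cutpoint goes to the lower tertile
  t3 <- aaci_tertiles(3.32, cutpoints = c(3.32, 3.57))
  expect_equal(as.character(t3), "T1")

  expect_error(aaci_tertiles(rep(2, 10)), class = "aaci_error_degenerate")
  expect_error(aaci_tertiles(c(1, 2)), class = "aaci_error_degenerate")
})

test_that("index output round-trips through the CSV writer with a sidecar", {
  res <- add_tertiles(compute_aaci(random_intakes(9, seed = 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  side <- write_aaci(res, path)
  expect_equal(side$cutpoints, attr(res, "cutpoints"))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$aaci, res$aaci, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
})
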
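test_that("single-item band lookups match the score sheet", {
  expect_equal(incns_item_points("temp_axillary", 39), 1L)
  expect_equal(incns_item_points("albumin", 40), 0L)
  # 19.35 rounds half-up to the 19.4 band boundary at one-decimal resolution
  expect_equal(incns_item_points("glucose", 19.35), 2L)
  expect_equal(incns_item_points("wbc", c(7, 3.5, 26, 2)), c(0L, 1L, 2L, 2L))
  expect_equal(incns_item_points("arousal", "eye_opening_to_pain"), 2L)
  expect_equal(incns_item_points("pupillary_reflex", "unilateral_impaired"), 2L)
  expect_error(incns_item_points("nonsense", 1), "unknown INCNS item")
  expect_error(incns_item_points("wbc", -1), "non-negative")
  expect_error(incns_item_points("wbc", NaN), "finite")
  expect_error(incns_item_points("arousal", "asleep"), "invalid value")
})

test_that("numeric items match an independent transcription of the sheet on a fine grid", {
  for (item in names(incns_oracle)) {
    grid <- incns_oracle_grid[[item]]
    expected <- vapply(grid, incns_oracle[[item]], numeric(1))
    expect_equal(incns_item_points(item, grid), as.integer(expected),
                 info = item)
  }
})

test_that("values between printed bands score in the adjacent more severe band", {
  expect_equal(incns_item_points("creatinine", 43.5), 1L)   # between 43 and 44
  expect_equal(incns_item_points("creatinine", 132.5), 1L)  # between 0 and 1 bands
  expect_equal(incns_item_points("creatinine", 171.5), 2L)
  expect_equal(incns_item_points("sbp", 89.5), 1L)
  expect_equal(incns_item_points("sbp", 140.5), 1L)
  expect_equal(incns_item_points("sbp", 199.5), 2L)
  expect_equal(incns_item_points("wbc", 10.04), 0L)  # rounds to 10.0
  expect_equal(incns_item_points("wbc", 10.05), 1L)  # rounds to 10.1
})

test_that("worked INCNS totals: all-normal 0, all-worst 44, mixed case 27", {
  expect_equal(score_incns(normal_observation())$total, 0L)
  expect_equal(score_incns(worst_observation())$total, 44L)

  mixed <- normal_observation()
  mixed$age_years <- 70; mixed$wbc <- 12; mixed$temp_axillary <- 39
  mixed$albumin <- 30; mixed$arousal <- "eye_opening_to_pain"
  mixed$awareness <- "none"; mixed$pupillary_reflex <- "unilateral_impaired"
  mixed$verbal <- "incomprehensible_or_none"
  mixed$strength_left <- 1; mixed$strength_right <- 0
  mixed$swallow <- "wst_III_IV_or_unassessable"
  mixed$intubated <- TRUE
  mixed$ventilator_breathing <- "above_ventilator_rate"
  mixed$heart_rate <- 110; mixed$sbp <- 150; mixed$glucose <- 15
  mixed$sodium <- 155; mixed$potassium <- 3.0; mixed$creatinine <- 150
  mixed$bilirubin <- 50
  expect_equal(score_incns(mixed)$total, 27L)
})

test_that("domain maxima computed from the tables sum to 44", {
  m <- incns_item_max()
  expect_equal(sum(m[c("wbc", "temp_axillary")]), 4)           # inflammation
  expect_equal(unname(m["albumin"]), 2)                        # nutrition
  expect_equal(sum(m[c("arousal", "awareness")]), 6)           # consciousness
  expect_equal(sum(m[c("pupillary_reflex", "corneal_reflex", "verbal",
                       "motor", "swallow", "respiration")]), 15) # neurologic
  expect_equal(sum(m[c("age_years", "heart_rate", "sbp", "glucose",
                       "sodium", "potassium", "creatinine",
                       "bilirubin")]), 17)                     # systemic
  expect_equal(max_score("incns"), 44L)
})

test_that("motor item follows the worse-limb strength rubric and the pain rubric", {
  strength_case <- function(l, r) {
    obs <- normal_observation()
    obs$strength_left <- l; obs$strength_right <- r
    score_incns(obs)$pts_motor
  }
  expect_equal(strength_case(5, 4), 0L)
  expect_equal(strength_case(4, 2), 1L)   # worse limb 2-3
  expect_equal(strength_case(3, 3), 1L)
  expect_equal(strength_case(5, 1), 2L)   # unilateral <= 1
  expect_equal(strength_case(0, 1), 3L)   # bilateral <= 1
  pain_case <- function(p) {
    obs <- normal_observation()
    obs$strength_left <- NA; obs$strength_right <- NA; obs$pain_response <- p
    score_incns(obs)$pts_motor
  }
  expect_equal(pain_case("obeying"), 0L)
  expect_equal(pain_case("localizing_or_withdrawal"), 1L)
  expect_equal(pain_case("flexing_or_extending"), 2L)
  expect_equal(pain_case("none"), 3L)
  # both rubrics supplied: strength wins, noted
  obs <- normal_observation()
  obs$pain_response <- "none"
  res <- score_incns(obs)
  expect_equal(res$pts_motor, 0L)
  expect_match(res$notes, "strength rubric")
})

test_that("respiration item distinguishes ventilation states and rate bands", {
  resp_case <- function(intubated, rate = NA, vent = NA) {
    obs <- normal_observation()
    obs$intubated <- intubated; obs$resp_rate <- rate
    obs$ventilator_breathing <- vent
    score_incns(obs)$pts_respiration
  }
  expect_equal(resp_case(FALSE, 16), 0L)
  expect_equal(resp_case(FALSE, 11), 1L)
  expect_equal(resp_case(FALSE, 25), 1L)
  expect_equal(resp_case(TRUE, 14, "above_ventilator_rate"), 2L)
  expect_equal(resp_case(TRUE, 14, "at_ventilator_rate_or_apnea"), 3L)
  expect_error(resp_case(TRUE, 14, NA), "ventilator_breathing")
})

test_that("missing items error by default and impute the normal band on request", {
  obs <- normal_observation()
  obs$albumin <- NA
  expect_error(score_incns(obs), "albumin")
  res <- score_incns(obs, assume_normal_missing = TRUE)
  expect_equal(res$pts_albumin, 0L)
  expect_match(res$notes, "assumed normal: albumin")
  expect_equal(res$total, 0L)
})

test_that("totals equal item sums, stay in range, and are monotone in single items", {
  withr::local_seed(421)
  pts_cols <- paste0("pts_", incns_items())
  for (i in 1:40) {
    res <- score_incns(random_observation())
    expect_equal(res$total, as.integer(sum(res[, pts_cols])))
    expect_gte(res$total, 0)
    expect_lte(res$total, 44)
  }
  # bump one numeric item into a more severe band: total never decreases
  worse_value <- list(
    wbc = c(12, 30), temp_axillary = c(39, 41), albumin = c(30, 20),
    glucose = c(15, 25), sodium = c(155, 165), potassium = c(6, 8),
    creatinine = c(150, 200), bilirubin = c(50, 150)
  )
  for (i in 1:30) {
    obs <- random_observation()
    base <- score_incns(obs)$total
    item <- sample(names(worse_value), 1)
    cur <- incns_item_points(item, obs[[item]])
    for (v in worse_value[[item]]) {
      if (incns_item_points(item, v) >= cur) {
        obs2 <- obs
        obs2[[item]] <- v
        expect_gte(score_incns(obs2)$total, base)
      }
    }
  }
})
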
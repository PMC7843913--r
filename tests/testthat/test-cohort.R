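make_outcomes <- function(ids, los = 200, drug = FALSE, died_nicu = FALSE,
                          mrs = 4) {
  tibble::tibble(
    patient_id = ids,
    nicu_los_hours = los,
    drug_induced_coma = drug,
    died_in_nicu = died_nicu,
    mrs_3month = mrs,
    died_by_3month = mrs == 6
  )
}

comatose_obs <- function(id, t = 0) {
  obs <- normal_observation(patient_id = id, t_hours = t)
  obs$gcs_eye <- 1; obs$gcs_verbal <- 1; obs$gcs_motor <- 4
  obs
}

test_that("coma eligibility follows the component criteria exactly", {
  expect_true(is_comatose(1, 2, 4))
  expect_true(is_comatose(1, 1, 1))
  expect_false(is_comatose(2, 2, 4))
  expect_false(is_comatose(1, 3, 4))
  expect_false(is_comatose(1, 2, 5))
  expect_error(is_comatose(0, 1, 1), "gcs_eye")
})

test_that("mRS dichotomizes at 3", {
  expect_equal(dichotomize_mrs(c(0, 2, 3, 6)),
               c("favorable", "favorable", "unfavorable", "unfavorable"))
  expect_error(dichotomize_mrs(7), "mrs")
})

scale_scorer_total <- function(sc, obs) {
  switch(sc,
    incns = score_incns(obs)$total, gcs = score_gcs(obs)$total,
    four = score_four(obs)$total, apache2 = score_apache2(obs)$total
  )
}

test_that("a single observation window reduces to scoring that observation", {
  withr::local_seed(17)
  obs <- random_observation()
  obs$t_hours <- 5
  for (sc in c("incns", "gcs", "four", "apache2")) {
    w <- worst_in_window(obs, sc, 24)
    expect_equal(w$total, scale_scorer_total(sc, obs))
  }
})

test_that("worst-in-window composes per-variable worst values, not worst totals", {
  obs1 <- normal_observation("p", t_hours = 5)
  obs1$wbc <- 30      # 2 points, sodium normal
  obs2 <- normal_observation("p", t_hours = 20)
  obs2$sodium <- 165  # 2 points, wbc normal
  obs <- dplyr::bind_rows(obs1, obs2)
  w <- worst_in_window(obs, "incns", 24)
  expect_equal(w$total, 4L)
  expect_equal(w$pts_wbc, 2L)
  expect_equal(w$pts_sodium, 2L)
  # the sensitivity-analysis alternative keeps the single worst observation
  expect_equal(worst_in_window(obs, "incns", 24, method = "worst_total")$total, 2L)
})

test_that("GCS window worst is the componentwise minimum", {
  a <- normal_observation("p", t_hours = 10)
  a$gcs_eye <- 2; a$gcs_verbal <- 2; a$gcs_motor <- 4
  b <- normal_observation("p", t_hours = 20)
  b$gcs_eye <- 1; b$gcs_verbal <- 3; b$gcs_motor <- 5
  w <- worst_in_window(dplyr::bind_rows(a, b), "gcs", 24)
  expect_equal(w$total, 7L)
  expect_equal(c(w$pts_eye, w$pts_verbal, w$pts_motor), c(1L, 2L, 4L))
})

test_that("window boundaries include admission time and exclude later observations", {
  a <- normal_observation("p", t_hours = 0)
  a$wbc <- 30
  b <- normal_observation("p", t_hours = 30)
  b$sodium <- 165
  obs <- dplyr::bind_rows(a, b)
  expect_equal(worst_in_window(obs, "incns", 24)$total, 2L)  # t=0 in, t=30 out
  expect_equal(worst_in_window(obs, "incns", 72)$total, 4L)
  only_late <- normal_observation("q", t_hours = 30)
  expect_error(worst_in_window(only_late, "incns", 24), "no observation inside")
})

test_that("cohort construction applies the inclusion rules with one logged reason each", {
  ids <- paste0("p", 1:5)
  obs <- dplyr::bind_rows(
    { o <- normal_observation(ids[1]); o$gcs_eye <- 3; o },  # awake
    comatose_obs(ids[2]),                                    # short stay
    comatose_obs(ids[3]),                                    # drug induced
    comatose_obs(ids[4]),
    comatose_obs(ids[5])
  )
  outc <- make_outcomes(ids)
  outc$nicu_los_hours[2] <- 48
  outc$drug_induced_coma[3] <- TRUE
  res <- build_cohort(obs, outc)
  expect_equal(nrow(res$cohort), 2)
  expect_setequal(res$cohort$patient_id, ids[4:5])
  expect_equal(nrow(res$exclusions), 3)
  expect_equal(
    res$exclusions$reason[match(ids[1:3], res$exclusions$patient_id)],
    c("non_comatose", "short_stay", "drug_induced")
  )
  # priority order: a patient violating several rules logs the first
  outc$nicu_los_hours[1] <- 48
  res2 <- build_cohort(obs, outc)
  expect_equal(res2$exclusions$reason[res2$exclusions$patient_id == ids[1]],
               "non_comatose")
})

test_that("observation CSV round-trips with empty cells as missing", {
  obs <- dplyr::bind_rows(normal_observation("a"), worst_observation("b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_setequal(names(back), names(obs))
  expect_equal(back$albumin, obs$albumin)
  expect_true(is.na(back$aado2[1]))  # empty cell read as NA
  expect_equal(score_incns(back)$total, c(0L, 44L))
  expect_error(read_observations(withr::local_tempfile(lines = "x,y\n1,2",
                                                       fileext = ".csv")),
               "lacks column")
})

test_that("empty input gives an empty cohort", {
  res <- build_cohort(normal_observation()[0, ], make_outcomes(character(0))[0, ])
  expect_equal(nrow(res$cohort), 0)
  expect_equal(nrow(res$exclusions), 0)
})

test_that("a NICU death propagates through all three outcomes", {
  obs <- comatose_obs("p1")
  outc <- make_outcomes("p1", died_nicu = TRUE, mrs = 6)
  row <- build_cohort(obs, outc)$cohort
  expect_true(row$outcome_nicu_death)
  expect_true(row$outcome_3m_death)
  expect_true(row$outcome_unfavorable)
})

test_that("inconsistent outcome tables are rejected", {
  obs <- comatose_obs("p1")
  bad <- make_outcomes("p1", died_nicu = TRUE, mrs = 4)
  expect_error(build_cohort(obs, bad), "NICU death")
  bad2 <- make_outcomes("p1", mrs = 6)
  bad2$died_by_3month <- FALSE
  expect_error(build_cohort(obs, bad2), "mRS 6")
})

test_that("on a simulated cohort: partition, window monotonicity, determinism", {
  sim <- simulate_cohort(sim_config(n_patients = 120), seed = 31)
  res <- build_cohort(sim$observations, sim$outcomes)
  expect_equal(nrow(res$cohort) + nrow(res$exclusions), nrow(sim$outcomes))
  expect_equal(anyDuplicated(res$exclusions$patient_id), 0L)
  co <- res$cohort
  expect_true(all(co$incns_72 >= co$incns_24))
  expect_true(all(co$apache2_72 >= co$apache2_24))
  expect_true(all(co$gcs_72 <= co$gcs_24))
  expect_true(all(co$four_72 <= co$four_24))
  expect_true(all(co$outcome_3m_death[co$outcome_nicu_death]))
  res2 <- build_cohort(sim$observations, sim$outcomes)
  expect_identical(res, res2)
})
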
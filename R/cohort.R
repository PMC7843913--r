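# Cohort construction: coma eligibility, worst-value windows, outcome
# dichotomization.

#' Coma eligibility from GCS components
#'
#' A patient is comatose when the eye response is 1, the verbal response is
#' at most 2 and the motor response is at most 4.
#'
#' @param gcs_eye,gcs_verbal,gcs_motor GCS components (vectorized).
#' @return Logical vector.
#' @examples
#' is_comatose(1, 2, 4)  # TRUE
#' is_comatose(2, 2, 4)  # FALSE
#' @export
is_comatose <- function(gcs_eye, gcs_verbal, gcs_motor) {
  check_integerish_range(gcs_eye, 1, 4, "gcs_eye")
  check_integerish_range(gcs_verbal, 1, 5, "gcs_verbal")
  check_integerish_range(gcs_motor, 1, 6, "gcs_motor")
  gcs_eye == 1 & gcs_verbal <= 2 & gcs_motor <= 4
}

#' Dichotomize the modified Rankin Scale
#'
#' mRS below 3 is a favorable 3-month functional outcome; 3-6 is unfavorable.
#'
#' @param mrs Integer vector in 0-6 (6 = dead).
#' @return Character vector, `"favorable"` or `"unfavorable"`.
#' @examples
#' dichotomize_mrs(c(2, 3))
#' @export
dichotomize_mrs <- function(mrs) {
  check_integerish_range(mrs, 0, 6, "mrs")
  ifelse(mrs < 3, "favorable", "unfavorable")
}

scale_scorer <- function(scale, assume_normal_missing = FALSE) {
  switch(tolower(scale),
    incns = function(d) score_incns(d, assume_normal_missing),
    gcs = score_gcs,
    four = score_four,
    apache2 = function(d) score_apache2(d, assume_normal_missing = assume_normal_missing),
    abort(paste0("unknown scale `", scale, "`"))
  )
}

#' Worst score in an observation window
#'
#' Scores each patient's most adverse presentation over the first
#' `window_hours` of NICU stay. By default each scored variable is taken at
#' its most points-adverse value independently across the in-window
#' observations and the composite is scored (per-variable worst, the
#' convention of worst-value severity scoring); `method = "worst_total"`
#' instead keeps the single observation with the most adverse total, for
#' sensitivity analysis. Observations at `t_hours` in `[0, window_hours]`
#' count as inside the window. For GCS and FOUR "adverse" is the lowest
#' component value; for INCNS and APACHE II it is the highest item points.
#'
#' @param data Observation data frame (any number of patients).
#' @param scale One of `"incns"`, `"gcs"`, `"four"`, `"apache2"`.
#' @param window_hours Window length, 24 or 72 in the validation design.
#' @param method `"per_variable"` (default) or `"worst_total"`.
#' @param assume_normal_missing Passed to the scorer.
#' @return Tibble with one row per patient: `patient_id`, per-item `pts_*`
#'   columns, `total`, `notes`, `scale`, `window_hours`, `n_obs`.
#' @export
worst_in_window <- function(data, scale, window_hours,
                            method = c("per_variable", "worst_total"),
                            assume_normal_missing = FALSE) {
  method <- match.arg(method)
  check_finite(window_hours, "window_hours")
  data <- tibble::as_tibble(data)
  if (!"t_hours" %in% names(data)) abort("`data` needs a `t_hours` column")
  inside <- is.finite(data$t_hours) & data$t_hours >= 0 &
    data$t_hours <= window_hours
  missing_pat <- setdiff(unique(data$patient_id), unique(data$patient_id[inside]))
  if (length(missing_pat) > 0) {
    abort(paste0("no observation inside the ", window_hours, "-h window for: ",
                 paste(utils::head(missing_pat, 5), collapse = ", ")))
  }
  scored <- scale_scorer(scale, assume_normal_missing)(data[inside, , drop = FALSE])
  pts_cols <- grep("^pts_", names(scored), value = TRUE)
  adverse_max <- scale_orientation(scale) == "higher_is_positive"

  if (method == "per_variable") {
    agg <- if (adverse_max) max else min
    out <- scored |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(pts_cols), agg),
        notes = join_notes(unique(.data$notes)),
        n_obs = dplyr::n(),
        .groups = "drop"
      )
    out$total <- as.integer(rowSums(as.matrix(out[pts_cols])))
  } else {
    out <- scored |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$t_hours, .by_group = TRUE) |>
      dplyr::mutate(n_obs = dplyr::n()) |>
      dplyr::slice(if (adverse_max) which.max(.data$total) else which.min(.data$total)) |>
      dplyr::ungroup() |>
      dplyr::select(-"t_hours", -"scale")
  }
  out$scale <- tolower(scale)
  out$window_hours <- window_hours
  dplyr::relocate(out, "patient_id", dplyr::all_of(pts_cols), "total",
                  "notes", "scale", "window_hours", "n_obs")
}

#' Build the analyzable cohort
#'
#' Applies the study inclusion rules and fills the eight window scores and
#' three nested binary outcomes for each eligible patient. A patient is kept
#' when the earliest recorded exam meets the coma criteria
#' ([is_comatose()]), the NICU stay lasted at least 72 h, and the coma was
#' not drug induced. Excluded patients are logged with one primary reason,
#' checked in that priority order.
#'
#' @param observations Observation data frame (standard layout), repeated
#'   observations per patient over the first 72 h.
#' @param outcomes Patient-level data frame with columns `patient_id`,
#'   `nicu_los_hours`, `drug_induced_coma`, `died_in_nicu`, `mrs_3month`
#'   (0-6, 6 = dead) and optionally `died_by_3month` (derived from
#'   `mrs_3month == 6` when absent).
#' @param assume_normal_missing,method Passed to [worst_in_window()].
#' @return List of class `coma_cohort` with elements `cohort` (tibble:
#'   `patient_id`, `incns_24`, `incns_72`, `gcs_24`, `gcs_72`, `four_24`,
#'   `four_72`, `apache2_24`, `apache2_72`, `outcome_unfavorable`,
#'   `outcome_nicu_death`, `outcome_3m_death`) and `exclusions` (tibble:
#'   `patient_id`, `reason`).
#' @export
build_cohort <- function(observations, outcomes,
                         assume_normal_missing = FALSE,
                         method = "per_variable") {
  observations <- tibble::as_tibble(observations)
  outcomes <- tibble::as_tibble(outcomes)
  observations$patient_id <- as.character(observations$patient_id)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  if (anyDuplicated(outcomes$patient_id)) {
    abort("`outcomes` must have one row per patient")
  }
  if (!setequal(unique(observations$patient_id), outcomes$patient_id)) {
    abort("`observations` and `outcomes` must cover the same patients")
  }
  if (!"died_by_3month" %in% names(outcomes)) {
    outcomes$died_by_3month <- outcomes$mrs_3month == 6
  }
  check_integerish_range(outcomes$mrs_3month, 0, 6, "mrs_3month")
  if (any(outcomes$died_in_nicu & !outcomes$died_by_3month)) {
    abort("invalid outcomes: NICU death implies 3-month death")
  }
  if (any(xor(outcomes$mrs_3month == 6, outcomes$died_by_3month))) {
    abort("invalid outcomes: mRS 6 must coincide with 3-month death")
  }

  empty_cohort <- tibble::tibble(
    patient_id = character(),
    incns_24 = integer(), incns_72 = integer(),
    gcs_24 = integer(), gcs_72 = integer(),
    four_24 = integer(), four_72 = integer(),
    apache2_24 = integer(), apache2_72 = integer(),
    outcome_unfavorable = logical(), outcome_nicu_death = logical(),
    outcome_3m_death = logical()
  )
  if (nrow(outcomes) == 0) {
    return(structure(
      list(cohort = empty_cohort,
           exclusions = tibble::tibble(patient_id = character(),
                                       reason = character())),
      class = "coma_cohort"
    ))
  }

  # eligibility judged on the earliest recorded exam
  first_exam <- observations |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$t_hours, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      comatose = is_comatose(.data$gcs_eye, .data$gcs_verbal, .data$gcs_motor)
    )
  elig <- outcomes |>
    dplyr::left_join(first_exam, by = "patient_id") |>
    dplyr::mutate(reason = dplyr::case_when(
      !.data$comatose ~ "non_comatose",
      .data$nicu_los_hours < 72 ~ "short_stay",
      .data$drug_induced_coma ~ "drug_induced",
      TRUE ~ NA_character_
    ))
  exclusions <- elig |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("patient_id", "reason")
  included <- elig |> dplyr::filter(is.na(.data$reason))

  if (nrow(included) == 0) {
    return(structure(list(cohort = empty_cohort, exclusions = exclusions),
                     class = "coma_cohort"))
  }
  obs_in <- observations |>
    dplyr::filter(.data$patient_id %in% included$patient_id)

  grid <- tidyr::expand_grid(
    scale = c("incns", "gcs", "four", "apache2"),
    window = c(24, 72)
  )
  scores <- purrr::pmap(grid, function(scale, window) {
    worst_in_window(obs_in, scale, window, method = method,
                    assume_normal_missing = assume_normal_missing) |>
      dplyr::select("patient_id", "total") |>
      setNames(c("patient_id", paste0(scale, "_", window)))
  }) |>
    purrr::reduce(dplyr::left_join, by = "patient_id")

  cohort <- included |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      outcome_unfavorable = dichotomize_mrs(.data$mrs_3month) == "unfavorable",
      outcome_nicu_death = as.logical(.data$died_in_nicu),
      outcome_3m_death = as.logical(.data$died_by_3month)
    ) |>
    dplyr::left_join(scores, by = "patient_id") |>
    dplyr::relocate(
      "patient_id", "incns_24", "incns_72", "gcs_24", "gcs_72", "four_24",
      "four_72", "apache2_24", "apache2_72", "outcome_unfavorable",
      "outcome_nicu_death", "outcome_3m_death"
    )
  structure(list(cohort = cohort, exclusions = exclusions),
            class = "coma_cohort")
}

#' @export
print.coma_cohort <- function(x, ...) {
  cat("<coma_cohort> ", nrow(x$cohort), " included patients, ",
      nrow(x$exclusions), " excluded\n", sep = "")
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  print(x$cohort, ...)
  invisible(x)
}
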
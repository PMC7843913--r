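# Observation table layout and example observation builders.

#' Columns of the standard observation table
#'
#' One row per timestamped patient observation; identifiers and demographics,
#' then the INCNS inputs (labs, vitals, neuro exam, ventilation), the extra
#' APACHE II physiology, and the GCS / FOUR components. An empty cell in a
#' CSV read with [read_observations()] is missing.
#'
#' @return Character vector of column names.
#' @export
observation_cols <- function() {
  c(
    "patient_id", "t_hours", "age_years", "wbc", "temp_axillary", "albumin",
    "arousal", "awareness", "pupillary_reflex", "corneal_reflex", "verbal",
    "strength_left", "strength_right", "pain_response", "swallow",
    "intubated", "resp_rate", "ventilator_breathing", "heart_rate", "sbp",
    "map", "glucose", "sodium", "potassium", "creatinine", "bilirubin",
    "pao2", "fio2", "aado2", "arterial_ph", "hematocrit",
    "acute_renal_failure", "chronic_health", "gcs_eye", "gcs_verbal",
    "gcs_motor", "four_eye", "four_motor", "four_brainstem",
    "four_respiration"
  )
}

#' Read / write observation tables
#'
#' Thin CSV readers/writers for the standard observation layout; empty cells
#' become `NA`.
#'
#' @param path File path.
#' @param data Data frame of observations.
#' @return `read_observations()` returns a tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
read_observations <- function(path) {
  out <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  )
  missing_cols <- setdiff(c("patient_id", "t_hours"), names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("observation CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out
}

#' @rdname read_observations
#' @export
write_observations <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Example observations
#'
#' `normal_observation()` is a healthy awake adult: every INCNS and
#' APACHE II item sits in its 0-point band, GCS 15, FOUR 16.
#' `worst_observation()` puts every item of every scale in its
#' maximum-point band (deep coma, ventilated at ventilator rate, acute renal
#' failure, emergency admission with severe chronic illness), so it attains
#' each scale's maximum: INCNS 44, APACHE II 71, GCS 3, FOUR 0.
#'
#' @param patient_id Identifier for the generated row.
#' @param t_hours Observation time in hours since admission.
#' @return One-row tibble in the standard observation layout.
#' @examples
#' score_incns(worst_observation())$total   # 44
#' @export
normal_observation <- function(patient_id = "p1", t_hours = 0) {
  tibble::tibble(
    patient_id = patient_id, t_hours = t_hours, age_years = 30,
    wbc = 7, temp_axillary = 36.8, albumin = 40,
    arousal = "spontaneous_eye_opening", awareness = "correct_response",
    pupillary_reflex = "bilateral_responsive",
    corneal_reflex = "bilateral_responsive", verbal = "accurate",
    strength_left = 5, strength_right = 5, pain_response = NA_character_,
    swallow = "wst_I_II", intubated = FALSE, resp_rate = 16,
    ventilator_breathing = NA_character_, heart_rate = 75, sbp = 120,
    map = 85, glucose = 5, sodium = 140, potassium = 4, creatinine = 80,
    bilirubin = 10, pao2 = 95, fio2 = 0.21, aado2 = NA_real_,
    arterial_ph = 7.4, hematocrit = 40, acute_renal_failure = FALSE,
    chronic_health = "none", gcs_eye = 4, gcs_verbal = 5, gcs_motor = 6,
    four_eye = 4, four_motor = 4, four_brainstem = 4, four_respiration = 4
  )
}

#' @rdname normal_observation
#' @export
worst_observation <- function(patient_id = "p1", t_hours = 0) {
  tibble::tibble(
    patient_id = patient_id, t_hours = t_hours, age_years = 80,
    wbc = 50, temp_axillary = 41.5, albumin = 15,
    arousal = "none", awareness = "none",
    pupillary_reflex = "bilateral_impaired",
    corneal_reflex = "bilateral_impaired",
    verbal = "incomprehensible_or_none",
    strength_left = 0, strength_right = 0, pain_response = "none",
    swallow = "wst_III_IV_or_unassessable", intubated = TRUE, resp_rate = 4,
    ventilator_breathing = "at_ventilator_rate_or_apnea", heart_rate = 200,
    sbp = 40, map = 200, glucose = 25, sodium = 190, potassium = 7.5,
    creatinine = 400, bilirubin = 150, pao2 = 40, fio2 = 1,
    aado2 = 600, arterial_ph = 6.9, hematocrit = 65,
    acute_renal_failure = TRUE, chronic_health = "emergency_or_nonoperative",
    gcs_eye = 1, gcs_verbal = 1, gcs_motor = 1,
    four_eye = 0, four_motor = 0, four_brainstem = 0, four_respiration = 0
  )
}
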
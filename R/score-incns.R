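#' Score observations on the INCNS scale
#'
#' Applies the 19-item INCNS severity score (range 0-44, higher = worse) to a
#' data frame of patient observations in the standard observation layout (see
#' [observation_cols()]). The motor item is scored from the worse limb when
#' Lovett strengths are supplied, otherwise from the pain-response rubric;
#' when both are present the strength rubric wins and a note is emitted.
#'
#' @param data Data frame of observations; one row per patient-observation.
#' @param assume_normal_missing If `TRUE`, a missing item is imputed at its
#'   0-point (normal) band and noted; the default is an error.
#' @return A tibble with one row per observation: `patient_id`, `t_hours`,
#'   one `pts_*` column per item, `total`, `notes` and `scale`.
#' @examples
#' obs <- normal_observation()
#' score_incns(obs)$total  # 0
#' @export
score_incns <- function(data, assume_normal_missing = FALSE) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  notes <- character(n)
  col_or_na <- function(col) {
    if (col %in% names(data)) data[[col]] else rep(NA, n)
  }

  impute <- function(values, item, normal) {
    miss <- is.na(values)
    if (!any(miss)) return(values)
    if (!assume_normal_missing) {
      abort(sprintf("missing `%s` in %d observation(s); set `assume_normal_missing = TRUE` to impute the 0-point band", item, sum(miss)))
    }
    notes[miss] <<- vapply(
      notes[miss], join_notes, character(1),
      paste0("assumed normal: ", item)
    )
    values[miss] <- normal
    values
  }

  pts <- list()
  numeric_normals <- c(
    wbc = 7, temp_axillary = 37, albumin = 40, age_years = 40,
    heart_rate = 80, sbp = 120, glucose = 5, sodium = 140, potassium = 4.2,
    creatinine = 80, bilirubin = 10
  )
  for (item in names(.incns_numeric_bands)) {
    v <- impute(as.numeric(col_or_na(item)), item, numeric_normals[[item]])
    pts[[item]] <- incns_numeric_points(item, v)
  }
  enum_normals <- c(
    arousal = "spontaneous_eye_opening", awareness = "correct_response",
    pupillary_reflex = "bilateral_responsive",
    corneal_reflex = "bilateral_responsive", verbal = "accurate",
    swallow = "wst_I_II"
  )
  for (item in names(enum_normals)) {
    v <- impute(as.character(col_or_na(item)), item, enum_normals[[item]])
    pts[[item]] <- incns_enum_points(item, v)
  }

  # motor: strength rubric preferred when both rubrics supplied
  sl <- as.numeric(col_or_na("strength_left"))
  sr <- as.numeric(col_or_na("strength_right"))
  pain <- as.character(col_or_na("pain_response"))
  has_strength <- !is.na(sl) & !is.na(sr)
  has_pain <- !is.na(pain)
  motor_pts <- rep(NA_integer_, n)
  if (any(has_strength)) {
    motor_pts[has_strength] <-
      incns_motor_strength_points(sl[has_strength], sr[has_strength])
  }
  both <- has_strength & has_pain
  if (any(both)) {
    notes[both] <- vapply(notes[both], join_notes, character(1),
                          "motor: strength rubric used over pain response")
  }
  use_pain <- !has_strength & has_pain
  if (any(use_pain)) {
    motor_pts[use_pain] <- incns_enum_points("pain_response", pain[use_pain])
  }
  miss_motor <- is.na(motor_pts)
  if (any(miss_motor)) {
    if (!assume_normal_missing) {
      abort("missing motor assessment (limb strengths or pain response) in some observations")
    }
    motor_pts[miss_motor] <- 0L
    notes[miss_motor] <- vapply(notes[miss_motor], join_notes, character(1),
                                "assumed normal: motor")
  }
  pts$motor <- motor_pts

  intub <- as.logical(impute(col_or_na("intubated"), "intubated", FALSE))
  rr <- as.numeric(col_or_na("resp_rate"))
  vent <- as.character(col_or_na("ventilator_breathing"))
  miss_resp <- (!intub & is.na(rr)) | (intub & is.na(vent))
  if (any(miss_resp)) {
    if (!assume_normal_missing) {
      abort("missing respiration inputs (`resp_rate` / `ventilator_breathing`) in some observations")
    }
    rr[!intub & is.na(rr)] <- 16
    intub[miss_resp & intub] <- FALSE
    rr[is.na(rr)] <- 16
    notes[miss_resp] <- vapply(notes[miss_resp], join_notes, character(1),
                               "assumed normal: respiration")
  }
  pts$respiration <- incns_respiration_points(intub, rr, vent)

  pts <- pts[incns_items()]
  names(pts) <- paste0("pts_", names(pts))
  pid <- if ("patient_id" %in% names(data)) {
    as.character(data$patient_id)
  } else {
    as.character(seq_len(n))
  }
  out <- tibble::tibble(
    patient_id = pid,
    t_hours = as.numeric(col_or_na("t_hours")),
    !!!pts
  )
  out$total <- as.integer(rowSums(as.matrix(out[paste0("pts_", incns_items())])))
  out$notes <- notes
  out$scale <- "incns"
  out
}
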
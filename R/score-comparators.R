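# GCS and FOUR comparator scales.

.gcs_component_range <- list(eye = c(1L, 4L), verbal = c(1L, 5L), motor = c(1L, 6L))
.four_component_range <- list(eye = c(0L, 4L), motor = c(0L, 4L),
                              brainstem = c(0L, 4L), respiration = c(0L, 4L))

#' Score observations on the Glasgow Coma Scale
#'
#' Sums the eye (1-4), verbal (1-5) and motor (1-6) components; total 3-15,
#' lower = worse. For intubated patients the verbal component cannot be
#' assessed and is scored 1, with a note.
#'
#' @param data Data frame with columns `gcs_eye`, `gcs_verbal`, `gcs_motor`
#'   and optionally `intubated` (default `FALSE`) plus `patient_id`/`t_hours`.
#' @return Tibble with per-component points, `total`, `notes`, `scale`.
#' @examples
#' score_gcs(data.frame(gcs_eye = 3, gcs_verbal = 4, gcs_motor = 6,
#'                      intubated = TRUE))$total  # 10
#' @export
score_gcs <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  eye <- check_integerish_range(as.numeric(data$gcs_eye),
                                1, 4, "gcs_eye")
  verbal <- check_integerish_range(as.numeric(data$gcs_verbal),
                                   1, 5, "gcs_verbal")
  motor <- check_integerish_range(as.numeric(data$gcs_motor),
                                  1, 6, "gcs_motor")
  intub <- if ("intubated" %in% names(data)) {
    as.logical(data$intubated) %in% TRUE
  } else {
    rep(FALSE, n)
  }
  notes <- character(n)
  coerced <- intub & verbal != 1
  verbal[intub] <- 1
  notes[coerced] <- "verbal set to 1 (intubated)"
  pid <- if ("patient_id" %in% names(data)) as.character(data$patient_id)
         else as.character(seq_len(n))
  tibble::tibble(
    patient_id = pid,
    t_hours = if ("t_hours" %in% names(data)) as.numeric(data$t_hours) else NA_real_,
    pts_eye = as.integer(eye),
    pts_verbal = as.integer(verbal),
    pts_motor = as.integer(motor),
    total = as.integer(eye + verbal + motor),
    notes = notes,
    scale = "gcs"
  )
}

#' Score observations on the FOUR scale
#'
#' Full Outline of UnResponsiveness: eye, motor, brainstem and respiration
#' components scored 0-4 each; total 0-16, lower = worse.
#'
#' @param data Data frame with columns `four_eye`, `four_motor`,
#'   `four_brainstem`, `four_respiration` (plus `patient_id`/`t_hours`).
#' @return Tibble with per-component points, `total`, `notes`, `scale`.
#' @examples
#' score_four(data.frame(four_eye = 2, four_motor = 3, four_brainstem = 1,
#'                       four_respiration = 0))$total  # 6
#' @export
score_four <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  comp <- lapply(names(.four_component_range), function(cmp) {
    rng <- .four_component_range[[cmp]]
    as.integer(check_integerish_range(
      as.numeric(data[[paste0("four_", cmp)]]), rng[1], rng[2],
      paste0("four_", cmp)
    ))
  })
  names(comp) <- paste0("pts_", names(.four_component_range))
  pid <- if ("patient_id" %in% names(data)) as.character(data$patient_id)
         else as.character(seq_len(n))
  tibble::tibble(
    patient_id = pid,
    t_hours = if ("t_hours" %in% names(data)) as.numeric(data$t_hours) else NA_real_,
    !!!comp,
    total = as.integer(Reduce(`+`, comp)),
    notes = "",
    scale = "four"
  )
}
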
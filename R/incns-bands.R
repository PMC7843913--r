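# INCNS item band tables.
#
# Each numeric item is a set of closed intervals [lo, hi] at one-decimal
# resolution, each carrying a point value; enum items are named point maps.
# The 19 items span five domains: inflammation (WBC, temperature), nutrition
# (albumin), consciousness (arousal, awareness), neurological function
# (pupillary and corneal reflexes, verbal, motor, swallowing, respiration)
# and systemic condition (age, heart rate, SBP, glucose, sodium, potassium,
# creatinine, bilirubin). Item maxima sum to 44.

incns_band <- function(lo, hi, points) {
  data.frame(lo = lo, hi = hi, points = points)
}

# Printed intervals are inclusive at both ends. The 2-point WBC band is the
# complement of the 0/1 bands (<= 2.8 or >= 25.1): the published sheet's cell
# for it is corrupted. The creatinine 0 band is 44-132 (the sheet prints
# "4.4-132", inconsistent with its 1-point band "<= 43").
.incns_numeric_bands <- list(
  wbc = incns_band(
    lo = c(4, 2.9, 10.1, -Inf, 25.1),
    hi = c(10, 3.9, 25.0, 2.8, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  temp_axillary = incns_band(
    lo = c(36, -Inf, 38.5, 40.1),
    hi = c(38.4, 35.9, 40, Inf),
    points = c(0L, 1L, 1L, 2L)
  ),
  albumin = incns_band(
    lo = c(35, 25, -Inf),
    hi = c(Inf, 34.9, 24.9),
    points = c(0L, 1L, 2L)
  ),
  age_years = incns_band(
    lo = c(-Inf, 45, 65, 75),
    hi = c(44, 64, 74, Inf),
    points = c(0L, 1L, 2L, 3L)
  ),
  heart_rate = incns_band(
    lo = c(60, 40, 101, -Inf, 150),
    hi = c(100, 59, 149, 39, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  sbp = incns_band(
    lo = c(90, 70, 141, -Inf, 200),
    hi = c(140, 89, 199, 69, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  glucose = incns_band(
    lo = c(3.9, 2.2, 11.2, -Inf, 19.4),
    hi = c(11.1, 3.8, 19.3, 2.1, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  sodium = incns_band(
    lo = c(130, 120, 151, -Inf, 160),
    hi = c(150, 129, 159, 119, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  potassium = incns_band(
    lo = c(3.5, 2.5, 5.6, -Inf, 7.0),
    hi = c(5.5, 3.4, 6.9, 2.4, Inf),
    points = c(0L, 1L, 1L, 2L, 2L)
  ),
  creatinine = incns_band(
    lo = c(44, -Inf, 133, 172),
    hi = c(132, 43, 171, Inf),
    points = c(0L, 1L, 1L, 2L)
  ),
  bilirubin = incns_band(
    lo = c(-Inf, 34.2, 102.6),
    hi = c(34.1, 102.5, Inf),
    points = c(0L, 1L, 2L)
  )
)

.incns_enum_points <- list(
  arousal = c(
    spontaneous_eye_opening = 0L, eye_opening_to_verbal = 1L,
    eye_opening_to_pain = 2L, none = 3L
  ),
  awareness = c(
    correct_response = 0L, confused_response = 1L,
    non_reflex_movements = 2L, none = 3L
  ),
  # the published sheet has no 1-point band for the reflex items
  pupillary_reflex = c(
    bilateral_responsive = 0L, unilateral_impaired = 2L,
    bilateral_impaired = 3L
  ),
  corneal_reflex = c(
    bilateral_responsive = 0L, unilateral_impaired = 2L,
    bilateral_impaired = 3L
  ),
  verbal = c(
    accurate = 0L, confused_or_inappropriate = 1L,
    incomprehensible_or_none = 2L
  ),
  pain_response = c(
    obeying = 0L, localizing_or_withdrawal = 1L,
    flexing_or_extending = 2L, none = 3L
  ),
  swallow = c(wst_I_II = 0L, wst_III_IV_or_unassessable = 1L)
)

#' Names of the 19 INCNS items
#'
#' @return Character vector of item identifiers in score-sheet order.
#' @export
incns_items <- function() {
  c(
    "wbc", "temp_axillary", "albumin", "arousal", "awareness",
    "pupillary_reflex", "corneal_reflex", "verbal", "motor", "swallow",
    "respiration", "age_years", "heart_rate", "sbp", "glucose", "sodium",
    "potassium", "creatinine", "bilirubin"
  )
}

# max points per item, computed from the band tables / rubric maps
incns_item_max <- function() {
  num <- vapply(.incns_numeric_bands, function(b) max(b$points), integer(1))
  enum <- vapply(.incns_enum_points, max, integer(1))
  strength_max <- max(incns_motor_strength_points(
    rep(0:5, each = 6), rep(0:5, times = 6)
  ))
  c(num, enum[setdiff(names(enum), "pain_response")],
    motor = max(strength_max, max(.incns_enum_points$pain_response)),
    respiration = max(.incns_respiration_map))
}

# Assign a numeric value to its band. Inputs are rounded half-up to one
# decimal (the band resolution) first; a value still falling between two
# printed bands is assigned to the adjacent band with more points
# (conservative: ambiguity scores as more severe).
incns_numeric_points <- function(item, value) {
  bands <- .incns_numeric_bands[[item]]
  check_finite(value, item)
  if (any(value < 0)) abort(paste0("`", item, "` must be non-negative"))
  v <- round_half_up(value, 1)
  vapply(v, function(x) {
    hit <- bands$points[bands$lo <= x & x <= bands$hi]
    if (length(hit) > 0) return(max(hit))
    below <- bands[bands$hi < x, , drop = FALSE]
    above <- bands[bands$lo > x, , drop = FALSE]
    adj <- c(
      if (nrow(below)) below$points[which.max(below$hi)],
      if (nrow(above)) above$points[which.min(above$lo)]
    )
    as.integer(max(adj))
  }, integer(1))
}

incns_enum_points <- function(item, value) {
  map <- .incns_enum_points[[item]]
  value <- as.character(value)
  bad <- setdiff(unique(value), names(map))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid value(s) for `%s`: %s (expected one of %s)",
      item, paste(bad, collapse = ", "), paste(names(map), collapse = ", ")
    ))
  }
  unname(map[value])
}

# motor item from limb strength (Lovett 0-5); scored from the worse limb
incns_motor_strength_points <- function(left, right) {
  check_integerish_range(left, 0, 5, "strength_left")
  check_integerish_range(right, 0, 5, "strength_right")
  n_weak <- (left <= 1) + (right <= 1)
  dplyr::case_when(
    n_weak == 2 ~ 3L,
    n_weak == 1 ~ 2L,
    pmin(left, right) <= 3 ~ 1L,
    TRUE ~ 0L
  )
}

.incns_respiration_map <- c(
  not_intubated_normal_rate = 0L, not_intubated_abnormal_rate = 1L,
  above_ventilator_rate = 2L, at_ventilator_rate_or_apnea = 3L
)

incns_respiration_points <- function(intubated, resp_rate, ventilator_breathing) {
  intubated <- as.logical(intubated)
  out <- integer(length(intubated))
  vent <- as.character(ventilator_breathing)
  if (any(intubated & !vent %in% c("above_ventilator_rate", "at_ventilator_rate_or_apnea"))) {
    abort("intubated observations need `ventilator_breathing` of above_ventilator_rate or at_ventilator_rate_or_apnea")
  }
  out[intubated] <- .incns_respiration_map[vent[intubated]]
  if (any(!intubated)) {
    rr <- resp_rate[!intubated]
    check_finite(rr, "resp_rate")
    rr <- round_half_up(rr, 0)
    out[!intubated] <- ifelse(
      rr >= 12 & rr <= 24,
      .incns_respiration_map[["not_intubated_normal_rate"]],
      .incns_respiration_map[["not_intubated_abnormal_rate"]]
    )
  }
  out
}

#' Points for a single INCNS item
#'
#' Looks up the band points for one of the 19 items of the INCNS severity
#' score. Numeric inputs are rounded half-up to the one-decimal band
#' resolution before assignment; a value between two printed bands is scored
#' in the adjacent band with more points.
#'
#' @param item Item identifier, one of [incns_items()] (plus the raw motor
#'   inputs `"pain_response"`).
#' @param value The measurement (numeric items), the level label (enum
#'   items), or for `"motor"` a list with `strength_left`/`strength_right` or
#'   `pain_response`; for `"respiration"` a list with `intubated`,
#'   `resp_rate`, `ventilator_breathing`.
#' @return Integer points.
#' @examples
#' incns_item_points("temp_axillary", 39)   # 1
#' incns_item_points("albumin", 40)         # 0
#' incns_item_points("glucose", 19.35)      # 2
#' @export
incns_item_points <- function(item, value) {
  if (!is.character(item) || length(item) != 1) abort("`item` must be one string")
  if (item %in% names(.incns_numeric_bands)) {
    return(incns_numeric_points(item, value))
  }
  if (item %in% c(names(.incns_enum_points))) {
    return(incns_enum_points(item, value))
  }
  if (item == "motor") {
    v <- value
    if (!is.null(v$strength_left) && !is.na(v$strength_left[1])) {
      return(incns_motor_strength_points(v$strength_left, v$strength_right))
    }
    return(incns_enum_points("pain_response", v$pain_response))
  }
  if (item == "respiration") {
    return(incns_respiration_points(value$intubated, value$resp_rate,
                                    value$ventilator_breathing))
  }
  abort(paste0("unknown INCNS item `", item, "`"))
}
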
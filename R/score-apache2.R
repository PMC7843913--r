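# APACHE II comparator (Knaus et al.'s point tables, SI units for
# creatinine). Total = acute physiology score (12 variables) + age points +
# chronic health points; maximum achievable total is 71.
#
# Each acute-physiology variable is a contiguous banding of the real line
# given as left-closed breaks plus the point value of each interval
# (points[i] applies to [breaks[i-1], breaks[i])).

apache_var <- function(breaks, points) list(breaks = breaks, points = points)

.apache2_bands <- list(
  temp = apache_var(c(30, 32, 34, 36, 38.5, 39, 41),
                    c(4L, 3L, 2L, 1L, 0L, 1L, 3L, 4L)),
  map = apache_var(c(50, 70, 110, 130, 160),
                   c(4L, 2L, 0L, 2L, 3L, 4L)),
  heart_rate = apache_var(c(40, 55, 70, 110, 140, 180),
                          c(4L, 3L, 2L, 0L, 2L, 3L, 4L)),
  resp_rate = apache_var(c(6, 10, 12, 25, 35, 50),
                         c(4L, 2L, 1L, 0L, 1L, 3L, 4L)),
  aado2 = apache_var(c(200, 350, 500), c(0L, 2L, 3L, 4L)),
  pao2 = apache_var(c(55, 61, 71), c(4L, 3L, 1L, 0L)),
  arterial_ph = apache_var(c(7.15, 7.25, 7.33, 7.5, 7.6, 7.7),
                           c(4L, 3L, 2L, 0L, 1L, 3L, 4L)),
  sodium = apache_var(c(111, 120, 130, 150, 155, 160, 180),
                      c(4L, 3L, 2L, 0L, 1L, 2L, 3L, 4L)),
  potassium = apache_var(c(2.5, 3, 3.5, 5.5, 6, 7),
                         c(4L, 2L, 1L, 0L, 1L, 3L, 4L)),
  creatinine = apache_var(c(53, 132.6, 176.8, 309.4),   # umol/L
                          c(2L, 0L, 2L, 3L, 4L)),
  hematocrit = apache_var(c(20, 30, 46, 50, 60),
                          c(4L, 2L, 0L, 1L, 2L, 4L)),
  wbc = apache_var(c(1, 3, 15, 20, 40),
                   c(4L, 2L, 0L, 1L, 2L, 4L))
)

.apache2_age <- apache_var(c(45, 55, 65, 75), c(0L, 2L, 3L, 5L, 6L))
.apache2_chronic <- c(none = 0L, elective_postop = 2L,
                      emergency_or_nonoperative = 5L)

apache2_var_points <- function(var, value) {
  tab <- if (var == "age") .apache2_age else .apache2_bands[[var]]
  check_finite(value, var)
  tab$points[findInterval(value, tab$breaks) + 1L]
}

#' Score observations on APACHE II
#'
#' Acute Physiology and Chronic Health Evaluation II, used as a comparator
#' scale: 12 acute-physiology variables (GCS contributes `15 - GCS`;
#' creatinine points double under acute renal failure; oxygenation is scored
#' from the alveolar-arterial gradient when FiO2 >= 0.5 and from PaO2
#' otherwise) plus age and chronic-health points. Total 0-71, higher = worse.
#'
#' @param data Data frame of observations in the standard layout (see
#'   [observation_cols()]): needs `temp_axillary`, `map`, `heart_rate`,
#'   `resp_rate`, `pao2`/`fio2` (and `aado2` when `fio2 >= 0.5`),
#'   `arterial_ph`, `sodium`, `potassium`, `creatinine`, `hematocrit`, `wbc`,
#'   `acute_renal_failure`, `age_years`, `chronic_health` and the GCS
#'   components (unless `gcs_total` is given).
#' @param gcs_total Optional numeric vector of GCS totals (3-15); by default
#'   computed from the GCS columns via [score_gcs()].
#' @param assume_normal_missing If `TRUE`, missing variables are imputed at
#'   their 0-point band and noted; the default is an error.
#' @return Tibble with per-variable points, `total`, `notes`, `scale`.
#' @export
score_apache2 <- function(data, gcs_total = NULL, assume_normal_missing = FALSE) {
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
    notes[miss] <<- vapply(notes[miss], join_notes, character(1),
                           paste0("assumed normal: ", item))
    values[miss] <- normal
    values
  }

  src <- c(
    temp = "temp_axillary", map = "map", heart_rate = "heart_rate",
    resp_rate = "resp_rate", arterial_ph = "arterial_ph", sodium = "sodium",
    potassium = "potassium", creatinine = "creatinine",
    hematocrit = "hematocrit", wbc = "wbc"
  )
  normals <- c(
    temp = 37, map = 85, heart_rate = 80, resp_rate = 16, arterial_ph = 7.4,
    sodium = 140, potassium = 4.2, creatinine = 80, hematocrit = 40, wbc = 7
  )
  pts <- list()
  for (var in names(src)) {
    v <- impute(as.numeric(col_or_na(src[[var]])), src[[var]], normals[[var]])
    pts[[var]] <- apache2_var_points(var, v)
  }

  # oxygenation: A-aDO2 bands when FiO2 >= 0.5, PaO2 bands otherwise
  fio2 <- impute(as.numeric(col_or_na("fio2")), "fio2", 0.21)
  if (any(fio2 < 0 | fio2 > 1)) abort("`fio2` must be a fraction in [0, 1]")
  use_aado2 <- fio2 >= 0.5
  oxy <- integer(n)
  if (any(use_aado2)) {
    aado2 <- as.numeric(col_or_na("aado2"))[use_aado2]
    if (any(is.na(aado2))) {
      if (!assume_normal_missing) abort("missing `aado2` with fio2 >= 0.5")
      notes[use_aado2][is.na(aado2)] <-
        vapply(notes[use_aado2][is.na(aado2)], join_notes, character(1),
               "assumed normal: aado2")
      aado2[is.na(aado2)] <- 100
    }
    oxy[use_aado2] <- apache2_var_points("aado2", aado2)
  }
  if (any(!use_aado2)) {
    pao2 <- as.numeric(col_or_na("pao2"))[!use_aado2]
    if (any(is.na(pao2))) {
      if (!assume_normal_missing) abort("missing `pao2` with fio2 < 0.5")
      notes[!use_aado2][is.na(pao2)] <-
        vapply(notes[!use_aado2][is.na(pao2)], join_notes, character(1),
               "assumed normal: pao2")
      pao2[is.na(pao2)] <- 95
    }
    oxy[!use_aado2] <- apache2_var_points("pao2", pao2)
  }
  pts$oxygenation <- oxy

  arf <- as.logical(impute(col_or_na("acute_renal_failure"),
                           "acute_renal_failure", FALSE))
  pts$creatinine <- pts$creatinine * (1L + arf)

  if (is.null(gcs_total)) {
    gcs_total <- score_gcs(data)$total
  }
  check_integerish_range(gcs_total, 3, 15, "gcs_total")
  pts$gcs <- as.integer(15L - gcs_total)

  age <- impute(as.numeric(col_or_na("age_years")), "age_years", 40)
  pts$age <- apache2_var_points("age", age)

  chronic <- as.character(impute(col_or_na("chronic_health"),
                                 "chronic_health", "none"))
  bad <- setdiff(unique(chronic), names(.apache2_chronic))
  if (length(bad) > 0) {
    abort(paste0("invalid `chronic_health` value(s): ", paste(bad, collapse = ", ")))
  }
  pts$chronic_health <- unname(.apache2_chronic[chronic])

  names(pts) <- paste0("pts_", names(pts))
  pid <- if ("patient_id" %in% names(data)) as.character(data$patient_id)
         else as.character(seq_len(n))
  out <- tibble::tibble(
    patient_id = pid,
    t_hours = if ("t_hours" %in% names(data)) as.numeric(data$t_hours) else NA_real_,
    !!!pts
  )
  out$total <- as.integer(rowSums(as.matrix(out[names(pts)])))
  out$notes <- notes
  out$scale <- "apache2"
  out
}
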
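# Synthetic comatose-cohort generator.
#
# Single-latent-severity design: each patient carries a severity z; the three
# nested outcomes (unfavorable 3-month functional outcome > 3-month death >
# NICU death) partition patients into four ordered strata drawn at the
# configured prevalences, and z | stratum ~ N(m_s, 1) with stratum means
# solved so that each nested dichotomy attains the binormal mixture AUC
# Phi(latent_effect / sqrt(2)) on the latent scale. Every scorer input is a
# monotone (softplus) map of z plus per-item noise, so banding the items
# loses information but preserves the score-outcome association.

#' Closed-form binormal AUC
#'
#' AUC of a Gaussian score with class means `mu0` (negative) and `mu1`
#' (positive) and SDs `sd0`, `sd1`, for a higher-is-positive score:
#' `pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`. The calibration oracle for
#' the generator.
#'
#' @param mu0,mu1 Class means.
#' @param sd0,sd1 Class standard deviations (> 0).
#' @return AUC in `(0, 1)`.
#' @examples
#' closed_form_auc(0, 1, 1, 1)  # 0.7602
#' @export
closed_form_auc <- function(mu0, mu1, sd0 = 1, sd1 = 1) {
  if (any(c(sd0, sd1) <= 0)) abort("standard deviations must be positive")
  pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Latent effect for a target AUC
#'
#' Inverts [closed_form_auc()] for unit SDs:
#' `delta = sqrt(2) * qnorm(target_auc)`.
#'
#' @param target_auc Target AUC in `(0.5, 1)`.
#' @return Latent separation (standardized units).
#' @examples
#' calibrate_effect_for_auc(0.766)  # ~1.027
#' @export
calibrate_effect_for_auc <- function(target_auc) {
  check_finite(target_auc, "target_auc")
  if (any(target_auc <= 0.5 | target_auc >= 1)) {
    abort("`target_auc` must be in (0.5, 1)")
  }
  sqrt(2) * qnorm(target_auc)
}

#' Simulation configuration
#'
#' Defaults emulate the validation cohort: 271 analyzable patients, outcome
#' prevalences 83% unfavorable / 45% 3-month death / 9.6% NICU death
#' (properly nested), observations at 2, 12, 24, 48 and 72 h, a small
#' positive per-hour deterioration drift, and a latent effect calibrated for
#' a latent-scale AUC of 0.80. The `fraction_excluded` arms add extra
#' timelines violating each inclusion rule on top of `n_patients`.
#'
#' @param n_patients Number of analyzable (included) patients.
#' @param prevalence_unfavorable,prevalence_3m_death,prevalence_nicu_death
#'   Nested outcome prevalences (nicu <= 3m <= unfavorable).
#' @param latent_effect Separation between outcome classes on the latent
#'   severity scale, standardized units; see [calibrate_effect_for_auc()].
#' @param obs_schedule Observation times in hours, all in `(0, 72]`.
#' @param deterioration_drift Per-hour latent drift (>= 0).
#' @param item_noise_sd Per-item latent noise SD.
#' @param fraction_excluded Named fractions (of `n_patients`) for the
#'   `non_comatose`, `short_stay` and `drug_induced` exclusion arms.
#' @param fraction_lost_followup Fraction flagged lost to follow-up (these
#'   patients keep their outcomes; the flag lets callers drop them).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 271,
                       prevalence_unfavorable = 0.83,
                       prevalence_3m_death = 0.45,
                       prevalence_nicu_death = 0.096,
                       latent_effect = calibrate_effect_for_auc(0.8),
                       obs_schedule = c(2, 12, 24, 48, 72),
                       deterioration_drift = 0.004,
                       item_noise_sd = 0.5,
                       fraction_excluded = c(non_comatose = 0.04,
                                             short_stay = 0.05,
                                             drug_induced = 0.02),
                       fraction_lost_followup = 0) {
  cfg <- list(
    n_patients = n_patients,
    prevalence_unfavorable = prevalence_unfavorable,
    prevalence_3m_death = prevalence_3m_death,
    prevalence_nicu_death = prevalence_nicu_death,
    latent_effect = latent_effect,
    obs_schedule = sort(unique(obs_schedule)),
    deterioration_drift = deterioration_drift,
    item_noise_sd = item_noise_sd,
    fraction_excluded = fraction_excluded,
    fraction_lost_followup = fraction_lost_followup
  )
  prevs <- c(cfg$prevalence_nicu_death, cfg$prevalence_3m_death,
             cfg$prevalence_unfavorable)
  if (any(prevs <= 0) || any(prevs >= 1) || is.unsorted(prevs)) {
    abort("prevalences must be in (0, 1) and nested: nicu <= 3m death <= unfavorable")
  }
  if (cfg$n_patients < 2) abort("`n_patients` must be at least 2")
  if (length(cfg$obs_schedule) == 0) abort("`obs_schedule` must be non-empty")
  if (any(cfg$obs_schedule <= 0) || any(cfg$obs_schedule > 72)) {
    abort("`obs_schedule` times must lie in (0, 72]")
  }
  if (cfg$item_noise_sd < 0 || cfg$deterioration_drift < 0 ||
      cfg$latent_effect < 0) {
    abort("`item_noise_sd`, `deterioration_drift` and `latent_effect` must be >= 0")
  }
  if (any(cfg$fraction_excluded < 0) || cfg$fraction_lost_followup < 0) {
    abort("exclusion fractions must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

# stratum weights: favorable, unfavorable survivor, 3m death (not NICU),
# NICU death
stratum_weights <- function(cfg) {
  c(
    1 - cfg$prevalence_unfavorable,
    cfg$prevalence_unfavorable - cfg$prevalence_3m_death,
    cfg$prevalence_3m_death - cfg$prevalence_nicu_death,
    cfg$prevalence_nicu_death
  )
}

# mixture AUC of the latent score for dichotomy "stratum > k"
mixture_latent_auc <- function(means, weights, k) {
  pos <- seq_along(means) > k
  w_pos <- weights[pos] / sum(weights[pos])
  w_neg <- weights[!pos] / sum(weights[!pos])
  sum(outer(w_pos, w_neg) *
        outer(means[pos], means[!pos],
              function(a, b) closed_form_auc(b, a)))
}

# solve ordered stratum means so every nested dichotomy attains the target
# latent AUC Phi(delta / sqrt(2)); parameterized by log-increments
solve_stratum_means <- function(cfg) {
  if (cfg$latent_effect == 0) return(rep(0, 4))
  target <- closed_form_auc(0, cfg$latent_effect)
  w <- stratum_weights(cfg)
  obj <- function(par) {
    m <- c(0, cumsum(exp(par)))
    sum(vapply(1:3, function(k) {
      (mixture_latent_auc(m, w, k) - target)^2
    }, numeric(1)))
  }
  init <- log(rep(max(cfg$latent_effect, 0.1), 3))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-8) {
    abort("could not calibrate stratum means for the requested latent effect")
  }
  c(0, cumsum(exp(fit$par)))
}

softplus <- function(x) log1p(exp(pmin(x, 30)))

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# map per-observation latent severity into every scorer input; all arguments
# are row-aligned vectors, `first` marks each patient's earliest exam
severity_to_observation <- function(pid, t, z_obs, age, chronic, arf_prone,
                                    noise_sd, comatose_first, first) {
  n <- length(z_obs)
  zi <- function() z_obs + rnorm(n, sd = noise_sd)
  s <- function(z) softplus(z)
  lev <- function(z, breaks, levels) levels[findInterval(z, breaks) + 1L]

  z_gcs <- zi()
  gcs_eye <- 4L - findInterval(z_gcs, c(-2.8, -2.2, -1.6))
  gcs_verbal <- 5L - findInterval(zi(), c(-2.6, -2.0, -1.4, -0.8))
  gcs_motor <- 6L - findInterval(zi(), c(-2.6, -2.0, -1.3, -0.4, 0.9))
  fc <- first & comatose_first
  gcs_eye[fc] <- 1L
  gcs_verbal[fc] <- pmin(gcs_verbal[fc], 2L)
  gcs_motor[fc] <- pmin(gcs_motor[fc], 4L)
  fn <- first & !comatose_first
  gcs_eye[fn] <- pmax(gcs_eye[fn], 2L)

  z_int <- zi()
  intubated <- z_int > 0.8
  sbp <- round(clamp(125 - 16 * s(zi()) + rnorm(n, sd = 4), 35, 230))
  tibble::tibble(
    patient_id = pid, t_hours = t, age_years = age,
    wbc = round(clamp(6 + 3.2 * s(zi()) + rnorm(n, sd = 0.8), 0.3, 60), 1),
    temp_axillary = round(clamp(36.8 + 1.1 * s(zi()) + rnorm(n, sd = 0.25), 33, 42.5), 1),
    albumin = round(clamp(42 - 5 * s(zi()) + rnorm(n, sd = 1.5), 12, 55), 1),
    arousal = lev(zi(), c(-2.5, -1.5, 0.8),
                  c("spontaneous_eye_opening", "eye_opening_to_verbal",
                    "eye_opening_to_pain", "none")),
    awareness = lev(zi(), c(-2.5, -1.5, 0.5),
                    c("correct_response", "confused_response",
                      "non_reflex_movements", "none")),
    pupillary_reflex = lev(zi(), c(0.7, 1.8),
                           c("bilateral_responsive", "unilateral_impaired",
                             "bilateral_impaired")),
    corneal_reflex = lev(zi(), c(0.9, 2.0),
                         c("bilateral_responsive", "unilateral_impaired",
                           "bilateral_impaired")),
    verbal = lev(zi(), c(-2.2, -1.2),
                 c("accurate", "confused_or_inappropriate",
                   "incomprehensible_or_none")),
    strength_left = NA_real_, strength_right = NA_real_,
    pain_response = lev(zi(), c(-1.5, 0, 1.3),
                        c("obeying", "localizing_or_withdrawal",
                          "flexing_or_extending", "none")),
    swallow = ifelse(zi() > -1.5, "wst_III_IV_or_unassessable", "wst_I_II"),
    intubated = intubated,
    resp_rate = round(clamp(
      ifelse(intubated, 14 + rnorm(n, sd = 1.5),
             16 + 4 * s(zi()) + rnorm(n, sd = 2)), 4, 55)),
    ventilator_breathing = ifelse(
      !intubated, NA_character_,
      ifelse(z_int > 2, "at_ventilator_rate_or_apnea", "above_ventilator_rate")
    ),
    heart_rate = round(clamp(78 + 14 * s(zi()) + rnorm(n, sd = 5), 25, 210)),
    sbp = sbp,
    map = round(clamp(sbp - 25 + rnorm(n, sd = 4), 25, 190)),
    glucose = round(clamp(6 + 2.6 * s(zi()) + rnorm(n, sd = 0.8), 1.5, 40), 1),
    sodium = round(clamp(138 + 6 * s(zi()) + rnorm(n, sd = 2), 105, 185)),
    potassium = round(clamp(4.1 + 0.55 * s(zi()) + rnorm(n, sd = 0.25), 1.8, 9), 1),
    creatinine = round(clamp(85 + 30 * s(zi()) + rnorm(n, sd = 10), 25, 700)),
    bilirubin = round(clamp(12 + 12 * s(zi()) + rnorm(n, sd = 3), 2, 400), 1),
    pao2 = round(clamp(95 - 14 * s(zi()) + rnorm(n, sd = 5), 30, 120)),
    fio2 = round(clamp(0.21 + 0.18 * s(zi()), 0.21, 1), 2),
    aado2 = round(clamp(60 + 110 * s(zi()) + rnorm(n, sd = 15), 10, 650)),
    arterial_ph = round(clamp(7.42 - 0.05 * s(zi()) + rnorm(n, sd = 0.02), 6.7, 7.8), 2),
    hematocrit = round(clamp(41 - 2.5 * s(zi()) + rnorm(n, sd = 2), 12, 65), 1),
    acute_renal_failure = arf_prone & (zi() > 2),
    chronic_health = chronic,
    gcs_eye = clamp(gcs_eye, 1L, 4L),
    gcs_verbal = clamp(gcs_verbal, 1L, 5L),
    gcs_motor = clamp(gcs_motor, 1L, 6L),
    four_eye = clamp(4L - findInterval(z_gcs, c(-2.2, -1.4, -0.6, 0.6)), 0L, 4L),
    four_motor = clamp(4L - findInterval(zi(), c(-1.8, -1.0, -0.2, 1.0)), 0L, 4L),
    four_brainstem = clamp(4L - findInterval(zi(), c(-0.5, 0.4, 1.3, 2.2)), 0L, 4L),
    four_respiration = clamp(4L - findInterval(zi(), c(-1.2, -0.2, 0.8, 1.8)), 0L, 4L)
  )
}

#' Generate a synthetic comatose cohort
#'
#' Draws `n_patients` analyzable patient timelines (comatose at the first
#' exam, NICU stay >= 72 h, coma not drug induced) plus the configured
#' exclusion arms, with repeated observations on the configured schedule and
#' nested binary outcomes whose prevalences match the configuration in
#' expectation. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the generator uses its own RNG scope and leaves
#'   the global random state untouched.
#' @return A list of class `coma_sim`: `observations` (standard observation
#'   layout), `outcomes` (one row per patient: `patient_id`,
#'   `nicu_los_hours`, `drug_induced_coma`, `died_in_nicu`, `mrs_3month`,
#'   `died_by_3month`, `etiology`, `lost_to_followup`), `latent` (per
#'   patient: `z`, `stratum`, `arm`), `stratum_means` and `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 40), seed = 7)
#' nrow(sim$outcomes)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  check_integerish_range(seed, -2^31 + 1, 2^31 - 1, "seed")
  withr::with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  arms <- c(
    included = config$n_patients,
    round(config$fraction_excluded[c("non_comatose", "short_stay",
                                     "drug_induced")] * config$n_patients)
  )
  arms[is.na(arms)] <- 0
  n_tot <- sum(arms)
  arm <- rep(names(arms), times = arms)
  pid <- sprintf("pt%04d", seq_len(n_tot))

  means <- solve_stratum_means(config)
  stratum <- sample(1:4, n_tot, replace = TRUE, prob = stratum_weights(config))
  z <- means[stratum] + rnorm(n_tot)

  mrs <- integer(n_tot)
  mrs[stratum == 1] <- sample(0:2, sum(stratum == 1), replace = TRUE)
  mrs[stratum == 2] <- sample(3:5, sum(stratum == 2), replace = TRUE)
  mrs[stratum >= 3] <- 6L

  los <- pmax(72, round(stats::rlnorm(n_tot, log(300), 0.7)))
  short <- arm == "short_stay"
  los[short] <- round(runif(sum(short), 24, 71))
  # a short stay cannot end in NICU death after 72 h bookkeeping; keep the
  # outcome but their rows never reach the cohort
  age <- round(clamp(rnorm(n_tot, 55, 16), 18, 95))
  chronic <- sample(c("none", "emergency_or_nonoperative"), n_tot,
                    replace = TRUE, prob = c(0.85, 0.15))
  arf_prone <- runif(n_tot) < 0.3
  etiology <- sample(
    c("cerebral_infarction", "cns_infection", "cerebral_hemorrhage", "other"),
    n_tot, replace = TRUE, prob = c(0.325, 0.232, 0.18, 0.263)
  )
  lost <- runif(n_tot) < config$fraction_lost_followup

  outcomes <- tibble::tibble(
    patient_id = pid,
    nicu_los_hours = los,
    drug_induced_coma = arm == "drug_induced",
    died_in_nicu = stratum == 4 & !short,
    mrs_3month = mrs,
    died_by_3month = stratum >= 3,
    etiology = etiology,
    lost_to_followup = lost
  )

  times_per_patient <- lapply(seq_len(n_tot), function(i) {
    times <- config$obs_schedule[config$obs_schedule <= los[i]]
    if (length(times) == 0) times <- config$obs_schedule[1]
    times
  })
  n_obs <- lengths(times_per_patient)
  row_pat <- rep(seq_len(n_tot), n_obs)
  t_vec <- unlist(times_per_patient)
  first <- t_vec == rep(vapply(times_per_patient, min, numeric(1)), n_obs)
  observations <- severity_to_observation(
    pid = pid[row_pat], t = t_vec,
    z_obs = z[row_pat] + config$deterioration_drift * t_vec,
    age = age[row_pat], chronic = chronic[row_pat],
    arf_prone = arf_prone[row_pat],
    noise_sd = config$item_noise_sd,
    comatose_first = (arm != "non_comatose")[row_pat],
    first = first
  )

  structure(
    list(
      observations = observations,
      outcomes = outcomes,
      latent = tibble::tibble(patient_id = pid, z = z, stratum = stratum,
                              arm = arm),
      stratum_means = means,
      config = config
    ),
    class = "coma_sim"
  )
}

#' @export
print.coma_sim <- function(x, ...) {
  cat("<coma_sim> ", nrow(x$outcomes), " patients (",
      sum(x$latent$arm == "included"), " eligible), ",
      nrow(x$observations), " observations\n", sep = "")
  invisible(x)
}
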
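# Independent oracles used across tests.

# brute-force pairwise Mann-Whitney AUC
brute_auc <- function(scores, labels, orientation = "higher_is_positive") {
  s <- if (orientation == "lower_is_positive") -scores else scores
  p <- s[as.logical(labels)]
  n <- s[!as.logical(labels)]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive Youden search oracle: best (se + sp) over observed thresholds
brute_youden <- function(scores, labels, orientation = "higher_is_positive") {
  thr <- sort(unique(scores))
  grid <- confusion_at_cutoff(scores, labels, thr, orientation)
  max(grid$se + grid$sp)
}

# direct transcription of the printed INCNS numeric bands as if-chains
# (independent of the package's interval tables); defined at each item's
# printed resolution, so no gap handling is needed here
incns_oracle <- list(
  wbc = function(v) {
    if (v >= 4 && v <= 10) 0
    else if ((v >= 2.9 && v <= 3.9) || (v >= 10.1 && v <= 25.0)) 1
    else 2  # corrected complement band: <= 2.8 or >= 25.1
  },
  temp_axillary = function(v) {
    if (v >= 36 && v <= 38.4) 0
    else if (v <= 35.9 || (v >= 38.5 && v <= 40)) 1
    else 2
  },
  albumin = function(v) if (v >= 35) 0 else if (v >= 25) 1 else 2,
  age_years = function(v) {
    if (v <= 44) 0 else if (v <= 64) 1 else if (v <= 74) 2 else 3
  },
  heart_rate = function(v) {
    if (v >= 60 && v <= 100) 0
    else if ((v >= 40 && v <= 59) || (v >= 101 && v <= 149)) 1
    else 2
  },
  sbp = function(v) {
    if (v >= 90 && v <= 140) 0
    else if ((v >= 70 && v <= 89) || (v >= 141 && v <= 199)) 1
    else 2
  },
  glucose = function(v) {
    if (v >= 3.9 && v <= 11.1) 0
    else if ((v >= 2.2 && v <= 3.8) || (v >= 11.2 && v <= 19.3)) 1
    else 2
  },
  sodium = function(v) {
    if (v >= 130 && v <= 150) 0
    else if ((v >= 120 && v <= 129) || (v >= 151 && v <= 159)) 1
    else 2
  },
  potassium = function(v) {
    if (v >= 3.5 && v <= 5.5) 0
    else if ((v >= 2.5 && v <= 3.4) || (v >= 5.6 && v <= 6.9)) 1
    else 2
  },
  creatinine = function(v) {
    if (v >= 44 && v <= 132) 0
    else if (v <= 43 || (v >= 133 && v <= 171)) 1
    else 2
  },
  bilirubin = function(v) if (v <= 34.1) 0 else if (v <= 102.5) 1 else 2
)

# grids at each item's printed resolution (integers where the sheet prints
# integers, 0.1 steps where it prints one decimal), including all boundaries
incns_oracle_grid <- list(
  wbc = round(seq(0, 45, by = 0.1), 1),
  temp_axillary = round(seq(30, 43, by = 0.1), 1),
  albumin = round(seq(10, 60, by = 0.1), 1),
  age_years = 0:110,
  heart_rate = 0:220,
  sbp = 0:260,
  glucose = round(seq(0, 30, by = 0.1), 1),
  sodium = 90:200,
  potassium = round(seq(0, 10, by = 0.1), 1),
  creatinine = 0:400,
  bilirubin = round(seq(0, 200, by = 0.1), 1)
)

# random raw observation in the standard layout (not necessarily comatose)
random_observation <- function(id = "r1") {
  obs <- normal_observation(patient_id = id)
  obs$age_years <- sample(18:95, 1)
  obs$wbc <- round(runif(1, 0.5, 40), 1)
  obs$temp_axillary <- round(runif(1, 33, 42), 1)
  obs$albumin <- round(runif(1, 15, 50), 1)
  obs$arousal <- sample(names_arousal, 1)
  obs$awareness <- sample(names_awareness, 1)
  obs$pupillary_reflex <- sample(names_reflex, 1)
  obs$corneal_reflex <- sample(names_reflex, 1)
  obs$verbal <- sample(names_verbal, 1)
  if (runif(1) < 0.5) {
    obs$strength_left <- sample(0:5, 1)
    obs$strength_right <- sample(0:5, 1)
    obs$pain_response <- NA_character_
  } else {
    obs$strength_left <- NA_real_
    obs$strength_right <- NA_real_
    obs$pain_response <- sample(names_pain, 1)
  }
  obs$swallow <- sample(c("wst_I_II", "wst_III_IV_or_unassessable"), 1)
  obs$intubated <- runif(1) < 0.3
  obs$resp_rate <- sample(4:50, 1)
  obs$ventilator_breathing <- if (obs$intubated) {
    sample(c("above_ventilator_rate", "at_ventilator_rate_or_apnea"), 1)
  } else {
    NA_character_
  }
  obs$heart_rate <- sample(30:200, 1)
  obs$sbp <- sample(50:230, 1)
  obs$map <- obs$sbp - 25
  obs$glucose <- round(runif(1, 1.5, 30), 1)
  obs$sodium <- sample(105:185, 1)
  obs$potassium <- round(runif(1, 2, 9), 1)
  obs$creatinine <- sample(30:500, 1)
  obs$bilirubin <- round(runif(1, 2, 200), 1)
  obs$pao2 <- sample(35:110, 1)
  obs$fio2 <- round(runif(1, 0.21, 1), 2)
  obs$aado2 <- sample(20:600, 1)
  obs$arterial_ph <- round(runif(1, 6.9, 7.75), 2)
  obs$hematocrit <- round(runif(1, 15, 62), 1)
  obs$acute_renal_failure <- runif(1) < 0.2
  obs$chronic_health <- sample(c("none", "elective_postop",
                                 "emergency_or_nonoperative"), 1)
  obs$gcs_eye <- sample(1:4, 1)
  obs$gcs_verbal <- sample(1:5, 1)
  obs$gcs_motor <- sample(1:6, 1)
  obs$four_eye <- sample(0:4, 1)
  obs$four_motor <- sample(0:4, 1)
  obs$four_brainstem <- sample(0:4, 1)
  obs$four_respiration <- sample(0:4, 1)
  obs
}

names_arousal <- c("spontaneous_eye_opening", "eye_opening_to_verbal",
                   "eye_opening_to_pain", "none")
names_awareness <- c("correct_response", "confused_response",
                     "non_reflex_movements", "none")
names_reflex <- c("bilateral_responsive", "unilateral_impaired",
                  "bilateral_impaired")
names_verbal <- c("accurate", "confused_or_inappropriate",
                  "incomprehensible_or_none")
names_pain <- c("obeying", "localizing_or_withdrawal",
                "flexing_or_extending", "none")

# the six printed accuracy panels: outcome, window, Se%, Sp%, class sizes
printed_panels <- tibble::tribble(
  ~outcome,      ~window, ~se,   ~sp,   ~n_pos, ~n_neg, ~ppv,  ~npv,  ~cc,   ~accuracy,
  "functional",  24,      69.3,  71.7,  225,    46,     92.3,  32.4,  69.7,  70.5,
  "nicu_death",  24,      76.9,  88.2,  26,     245,    40.8,  97.3,  87.1,  82.6,
  "3m_death",    24,      64.8,  79.9,  122,    149,    72.5,  73.5,  73.1,  72.4,
  "functional",  72,      76.4,  78.3,  225,    46,     94.5,  40.4,  76.8,  77.4,
  "nicu_death",  72,      84.6,  82.5,  26,     245,    33.8,  98.1,  82.7,  83.6,
  "3m_death",    72,      70.5,  85.2,  122,    149,    79.6,  77.9,  78.6,  77.9
)
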
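# Small in-code fixtures shared across tests.

# A fully-populated session row builder: one row per element of `day`.
mk_sessions <- function(participant_id, day, score = 60, score2 = score,
                        pef = 400, wellbeing = "GOOD", pass1 = TRUE,
                        pass2 = TRUE, enroll = as.Date("2022-03-07")) {
  n <- length(day)
  tibble::tibble(
    participant_id = participant_id,
    session_time = as.POSIXct(enroll, tz = "UTC") + day * 86400 +
      9 * 3600 + seq_len(n) * 60,
    raw_score_1 = rep_len(score, n),
    raw_score_2 = rep_len(score2, n),
    elicitation_pass_1 = rep_len(pass1, n),
    elicitation_pass_2 = rep_len(pass2, n),
    elicitation_attempts_1 = 1L,
    elicitation_attempts_2 = 1L,
    pef_1 = rep_len(pef, n),
    pef_2 = NA_real_,
    pef_3 = NA_real_,
    wellbeing = rep_len(wellbeing, n),
    symptoms = "",
    triggers = "",
    severity_report = "none",
    rescue_use = "none_today"
  )
}

mk_participants <- function(ids, enroll = as.Date("2022-03-07")) {
  tibble::tibble(
    participant_id = ids,
    enrollment_date = enroll,
    sex = "female",
    age_years = 40L,
    ethnicity_hispanic = FALSE,
    race = "other",
    asthma_severity = "moderate_persistent",
    comorbidity_count = 1L,
    mental_health_any = FALSE
  )
}

mk_act <- function(ids = character(), dates = as.Date(character()),
                   scores = integer()) {
  tibble::tibble(participant_id = ids, act_date = dates,
                 act_score = as.integer(scores))
}

mk_ds <- function(sessions, act = NULL) {
  ids <- unique(sessions$participant_id)
  if (is.null(act)) act <- mk_act()
  study_dataset(mk_participants(ids), sessions, act)
}

# On-disk session column order (session_id is derived, not written).
.vb_test_session_cols <- function() {
  c("participant_id", "session_time", "raw_score_1", "raw_score_2",
    "elicitation_pass_1", "elicitation_pass_2",
    "elicitation_attempts_1", "elicitation_attempts_2",
    "pef_1", "pef_2", "pef_3", "wellbeing", "symptoms", "triggers",
    "severity_report", "rescue_use")
}

# Minimal labeled-session tibble for functions that consume scored data.
mk_scored <- function(participant_id, state, final_score,
                      day = seq_along(state),
                      zone = NULL, wellbeing = NULL,
                      enroll = as.Date("2022-03-07")) {
  n <- length(state)
  if (is.null(zone)) {
    zone <- ifelse(state == "NORMAL", "GREEN", "YELLOW")
  }
  if (is.null(wellbeing)) {
    wellbeing <- ifelse(state == "EXACERBATION", "NOT_GOOD", "GOOD")
  }
  tibble::tibble(
    session_id = sprintf("%s-s%04d", participant_id, seq_len(n)),
    participant_id = rep_len(participant_id, n),
    session_time = as.POSIXct(enroll, tz = "UTC") + day * 86400 + 9 * 3600,
    final_score = final_score,
    relative_pct = ifelse(zone == "GREEN", 100, 70),
    zone = zone,
    wellbeing = wellbeing,
    state = state,
    normalized_score = NA_real_
  )
}

# Run simulated data through QC, PEF and labeling, restricted to the
# analysis cohort (the common front half of the pipeline).
label_simulated <- function(ds, config = analysis_config()) {
  qc <- qc_pipeline(ds$sessions, config$consistency_threshold)
  pef <- pef_profiles(ds$sessions)
  scored <- label_sessions(ds$sessions, qc, pef)
  cohorts <- cohort_membership(ds, scored,
                               min_sessions = config$min_sessions,
                               min_normal = config$min_normal)
  scored[scored$participant_id %in%
           cohorts$participant_id[cohorts$analysis], , drop = FALSE]
}
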
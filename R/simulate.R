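# Synthetic-cohort simulator.
#
# Generates a study_dataset with the statistical structure the analysis
# assumes: engagement archetypes with heterogeneous monthly session
# counts, a daily latent 3-state respiratory process per participant,
# and per-session emissions (paired biomarker scores around a
# participant baseline plus a state shift, peak-flow readings around a
# latent personal best at a state-dependent relative level, well-being
# consistent with the state definition, elicitation pass/fail flags,
# and monthly ACT scores driven by trailing state burden). The latent
# truth is attached so parameter-recovery tests can compare estimates
# against it.

#' Simulator configuration
#'
#' Free parameters of the synthetic cohort. Defaults reproduce the
#' study conditions the pipeline is designed for: 84 participants over
#' 90 days, an engagement mix of 33/25/42% high/medium/low archetypes,
#' latent state marginals near 61.5/27.8/10.7%
#' (normal/mild/exacerbation), a mean score baseline of 61.7 with
#' state shifts of +3 (mild) and +8 (exacerbation), per-attempt
#' elicitation failure probabilities 13.3/35.3/44.6%, and a
#' within-session score disagreement calibrated so about 79% of
#' dual-pass sessions agree within 10 points.
#'
#' @param n_participants,study_days Cohort size and duration.
#' @param seed Integer seed; identical configs give identical datasets.
#' @param engagement_mix Named proportions over
#'   `high`/`medium`/`low` archetypes (must sum to 1).
#' @param state_marginal_target Named stationary proportions over
#'   `NORMAL`/`MILD`/`EXACERBATION` (must sum to 1).
#' @param state_persistence Daily probability of holding yesterday's
#'   state; otherwise the state is redrawn from the stationary target,
#'   so the marginal distribution equals the target exactly.
#' @param state_transition_matrix Optional explicit 3x3 row-stochastic
#'   matrix (rows/cols NORMAL, MILD, EXACERBATION); overrides the
#'   persistence construction.
#' @param baseline_score_mean,baseline_score_sd Between-participant
#'   distribution of the normal-function score baseline.
#' @param state_score_shift Named additive score shifts for `MILD` and
#'   `EXACERBATION` sessions.
#' @param within_session_score_sd Day-to-day score noise (shared by the
#'   session's two samples).
#' @param two_sample_extra_sd Independent per-sample noise controlling
#'   within-session score disagreement.
#' @param personal_best_mean_lpm,personal_best_sd_lpm Latent personal
#'   best distribution (L/min, truncated to 250--900).
#' @param elicitation_fail_probs Per-attempt failure probabilities
#'   (attempts 1--3).
#' @param second_sample_missing_prob Probability a session records only
#'   one voice sample.
#' @param pef_missing_prob Probability a session has no PEF reading.
#' @param pef_error_prob Probability of an erroneous >1000 L/min reading.
#' @param mild_pef_only_prob For mild-event sessions, probability the
#'   PEF criterion (rather than the well-being criterion) is the one met.
#' @param wellbeing_bad_prob Named probabilities that an impaired
#'   well-being response is `BAD` rather than `NOT_GOOD`, for `MILD` and
#'   `EXACERBATION` sessions.
#' @param act_noise_sd,act_completion_prob ACT score noise and monthly
#'   completion probability.
#' @param state_dependent_missingness If `TRUE`, sessions on
#'   exacerbation days are dropped with probability 0.3 (stress-tests
#'   informative missingness; off by default -- app use is modeled as
#'   self-directed but state-independent).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 84, study_days = 90, seed = 1,
                          engagement_mix = c(high = 0.33, medium = 0.25,
                                             low = 0.42),
                          state_marginal_target = c(NORMAL = 0.615,
                                                    MILD = 0.278,
                                                    EXACERBATION = 0.107),
                          state_persistence = 0.6,
                          state_transition_matrix = NULL,
                          baseline_score_mean = 61.7,
                          baseline_score_sd = 10,
                          state_score_shift = c(MILD = 3, EXACERBATION = 8),
                          within_session_score_sd = 6,
                          two_sample_extra_sd = 5.6,
                          personal_best_mean_lpm = 420,
                          personal_best_sd_lpm = 80,
                          elicitation_fail_probs = c(0.133, 0.353, 0.446),
                          second_sample_missing_prob = 0.066,
                          pef_missing_prob = 0.02,
                          pef_error_prob = 0.003,
                          mild_pef_only_prob = 0.6,
                          wellbeing_bad_prob = c(MILD = 0.034,
                                                 EXACERBATION = 0.13),
                          act_noise_sd = 2.5,
                          act_completion_prob = 0.7,
                          state_dependent_missingness = FALSE) {
  if (is.null(state_transition_matrix)) {
    p <- state_persistence
    pi_ <- state_marginal_target / sum(state_marginal_target)
    state_transition_matrix <- p * diag(3) +
      (1 - p) * matrix(pi_, 3, 3, byrow = TRUE)
    dimnames(state_transition_matrix) <- list(.vb_states, .vb_states)
  }
  cfg <- structure(
    list(
      n_participants = n_participants, study_days = study_days, seed = seed,
      engagement_mix = engagement_mix,
      state_marginal_target = state_marginal_target,
      state_persistence = state_persistence,
      state_transition_matrix = state_transition_matrix,
      baseline_score_mean = baseline_score_mean,
      baseline_score_sd = baseline_score_sd,
      state_score_shift = state_score_shift,
      within_session_score_sd = within_session_score_sd,
      two_sample_extra_sd = two_sample_extra_sd,
      personal_best_mean_lpm = personal_best_mean_lpm,
      personal_best_sd_lpm = personal_best_sd_lpm,
      elicitation_fail_probs = elicitation_fail_probs,
      second_sample_missing_prob = second_sample_missing_prob,
      pef_missing_prob = pef_missing_prob,
      pef_error_prob = pef_error_prob,
      mild_pef_only_prob = mild_pef_only_prob,
      wellbeing_bad_prob = wellbeing_bad_prob,
      act_noise_sd = act_noise_sd,
      act_completion_prob = act_completion_prob,
      state_dependent_missingness = state_dependent_missingness
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly; errors describe the first violated
#'   constraint.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_participants < 1 || config$study_days < 1) {
    stop("n_participants and study_days must be positive", call. = FALSE)
  }
  if (abs(sum(config$engagement_mix) - 1) > 1e-9) {
    stop("engagement_mix must sum to 1", call. = FALSE)
  }
  if (abs(sum(config$state_marginal_target) - 1) > 1e-9) {
    stop("state_marginal_target must sum to 1", call. = FALSE)
  }
  tm <- config$state_transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != c(3, 3)) ||
      any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0) || any(tm > 1)) {
    stop("state_transition_matrix must be 3x3 row-stochastic", call. = FALSE)
  }
  probs <- c(config$elicitation_fail_probs, config$second_sample_missing_prob,
             config$pef_missing_prob, config$pef_error_prob,
             config$mild_pef_only_prob, config$wellbeing_bad_prob,
             config$act_completion_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(config)
}

# Truncated-normal draws via inverse-CDF.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Monthly session counts per participant given the archetype:
# high ~22/month stable, medium ~16 declining to ~8, low ~6 with a
# steep quit cascade. Returns an n x 3 matrix.
.monthly_counts <- function(archetype) {
  n <- length(archetype)
  counts <- matrix(0L, n, 3)
  hi <- archetype == "high"
  if (any(hi)) {
    rate <- pmin(pmax(rnorm(sum(hi), 22, 5), 16), 28)
    for (m in 1:3) {
      counts[hi, m] <- pmin(30L, pmax(as.integer(round(
        rate + rnorm(sum(hi), 0, 2))), 14L))
    }
  }
  md <- archetype == "medium"
  if (any(md)) {
    frailty <- runif(sum(md), 0.8, 1.2)
    for (m in 1:3) {
      counts[md, m] <- pmin(30L, rpois(sum(md), c(16, 12, 8)[m] * frailty))
    }
    quit3 <- runif(sum(md)) < 0.12
    counts[md, 3][quit3] <- 0L
  }
  lo <- archetype == "low"
  if (any(lo)) {
    counts[lo, 1] <- pmin(30L, rpois(sum(lo), 6))
    active2 <- runif(sum(lo)) >= 0.45
    counts[lo, 2][active2] <- pmin(30L, rpois(sum(active2), 4))
    active3 <- active2 & runif(sum(lo)) >= 0.45
    counts[lo, 3][active3] <- pmin(30L, rpois(sum(active3), 4))
  }
  counts
}

#' Simulate a synthetic study cohort
#'
#' Deterministic given the config's seed. See [cohort_config()] for the
#' generative model. The latent truth (per-participant baseline score,
#' personal best and archetype; per-session latent state) is attached
#' as `attr(ds, "latent")`.
#'
#' @param config A [cohort_config()].
#' @return A `study_dataset`.
#' @examples
#' ds <- simulate_cohort(cohort_config(n_participants = 5, study_days = 30,
#'                                     seed = 7))
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  days <- config$study_days

  ids <- sprintf("P%03d", seq_len(n))
  enrollment <- as.Date("2022-01-03") + sample(0:365, n, replace = TRUE)
  participants <- tibble::tibble(
    participant_id = ids,
    enrollment_date = enrollment,
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(0.81, 0.19)),
    age_years = as.integer(pmax(18, round(rnorm(n, 39.8, 11.6)))),
    ethnicity_hispanic = runif(n) < 0.58,
    race = sample(c("black", "white", "other"), n, replace = TRUE,
                  prob = c(0.44, 0.15, 0.41)),
    asthma_severity = sample(.vb_asthma_severity, n, replace = TRUE,
                             prob = c(0.06, 0.37, 0.33, 0.24)),
    comorbidity_count = rpois(n, 2.5),
    mental_health_any = runif(n) < 0.46
  )

  archetype <- sample(names(config$engagement_mix), n, replace = TRUE,
                      prob = config$engagement_mix)
  baseline <- rnorm(n, config$baseline_score_mean, config$baseline_score_sd)
  pb <- pmin(pmax(rnorm(n, config$personal_best_mean_lpm,
                        config$personal_best_sd_lpm), 250), 900)

  # Latent daily state path (1 = NORMAL, 2 = MILD, 3 = EXACERBATION).
  tm <- config$state_transition_matrix
  pi_ <- config$state_marginal_target / sum(config$state_marginal_target)
  states <- matrix(0L, n, days)
  states[, 1] <- sample.int(3, n, replace = TRUE, prob = pi_)
  if (days > 1) {
    cum_tm <- t(apply(tm, 1, cumsum))
    for (t in 2:days) {
      u <- runif(n)
      prev <- states[, t - 1]
      states[, t] <- 1L + (u > cum_tm[prev, 1]) + (u > cum_tm[prev, 2])
    }
  }

  # Session days per participant (at most one session per calendar day).
  monthly <- .monthly_counts(archetype)
  n_months <- ceiling(days / 30)
  sess_list <- vector("list", n)
  for (i in seq_len(n)) {
    day_set <- integer(0)
    for (m in seq_len(min(3, n_months))) {
      lo_d <- (m - 1) * 30
      hi_d <- min(m * 30, days) - 1
      if (lo_d > hi_d) break
      pool <- lo_d:hi_d
      k <- min(monthly[i, m], length(pool))
      if (k > 0) day_set <- c(day_set, sort(sample(pool, k)))
    }
    sess_list[[i]] <- day_set
  }
  n_sess <- lengths(sess_list)
  si <- rep(seq_len(n), n_sess)      # participant index per session
  sday <- unlist(sess_list)
  sstate <- states[cbind(si, sday + 1)]

  if (config$state_dependent_missingness) {
    keep <- !(sstate == 3L & runif(length(si)) < 0.3)
    si <- si[keep]
    sday <- sday[keep]
    sstate <- sstate[keep]
  }
  ns <- length(si)

  # Scores: participant baseline + state shift + shared day noise +
  # independent per-sample noise.
  shift <- c(0, config$state_score_shift[["MILD"]],
             config$state_score_shift[["EXACERBATION"]])[sstate]
  day_mean <- baseline[si] + shift + rnorm(ns, 0, config$within_session_score_sd)
  clamp01 <- function(x) round(pmin(pmax(x, 0), 100), 2)  # app-scale scores
  raw1 <- clamp01(day_mean + rnorm(ns, 0, config$two_sample_extra_sd))
  raw2 <- clamp01(day_mean + rnorm(ns, 0, config$two_sample_extra_sd))

  # Elicitation check: up to three attempts per sample.
  elicit <- function(k) {
    p <- config$elicitation_fail_probs
    f1 <- runif(k) < p[1]
    f2 <- f1 & (runif(k) < p[2])
    f3 <- f2 & (runif(k) < p[3])
    list(pass = !f3, attempts = ifelse(!f1, 1L, ifelse(!f2, 2L, 3L)))
  }
  e1 <- elicit(ns)
  e2 <- elicit(ns)
  missing2 <- runif(ns) < config$second_sample_missing_prob
  raw1[!e1$pass] <- NA_real_
  raw2[!e2$pass | missing2] <- NA_real_
  pass2 <- e2$pass & !missing2
  att2 <- ifelse(missing2, NA_integer_, e2$attempts)

  # Relative PEF and well-being, jointly consistent with the state.
  pef_only <- sstate == 2L & runif(ns) < config$mild_pef_only_prob
  reduced <- sstate == 3L | pef_only
  rel <- numeric(ns)
  rel[!reduced] <- .rtruncnorm(sum(!reduced), 0.93, 0.06, 0.805, 1.02)
  rel[reduced] <- .rtruncnorm(sum(reduced), 0.68, 0.10, 0.25, 0.795)

  impaired_wb <- sstate == 3L | (sstate == 2L & !pef_only)
  bad_p <- ifelse(sstate == 3L, config$wellbeing_bad_prob[["EXACERBATION"]],
                  config$wellbeing_bad_prob[["MILD"]])
  wellbeing <- ifelse(
    impaired_wb,
    ifelse(runif(ns) < bad_p, "BAD", "NOT_GOOD"),
    "GOOD"
  )

  best_read <- round(pb[si] * rel)
  pef <- cbind(best_read,
               round(best_read * runif(ns, 0.93, 0.995)),
               round(best_read * runif(ns, 0.93, 0.995)))
  n_read <- sample.int(3, ns, replace = TRUE, prob = c(0.05, 0.15, 0.8))
  pef[n_read < 3, 3] <- NA_real_
  pef[n_read < 2, 2] <- NA_real_
  err <- runif(ns) < config$pef_error_prob
  pef[err, 2] <- round(runif(sum(err), 1010, 1990))
  no_pef <- runif(ns) < config$pef_missing_prob
  pef[no_pef, ] <- NA_real_

  # Patient-reported fields, state-dependent.
  sym_prob <- rbind(  # rows: states; cols: .vb_symptoms
    NORMAL = c(0.08, 0.08, 0.09, 0.06, 0.24),
    MILD = c(0.30, 0.18, 0.22, 0.15, 0.35),
    EXACERBATION = c(0.73, 0.37, 0.45, 0.25, 0.60)
  )
  trg_prob <- rbind(
    NORMAL = c(0.36, 0.23, 0.20, 0.25, 0.12, 0.34),
    MILD = c(0.40, 0.25, 0.22, 0.25, 0.12, 0.36),
    EXACERBATION = c(0.53, 0.30, 0.15, 0.35, 0.15, 0.72)
  )
  draw_tokens <- function(prob_mat, vocab) {
    hits <- matrix(runif(ns * length(vocab)), ns) < prob_mat[sstate, ]
    apply(hits, 1, function(h) paste(vocab[h], collapse = ";"))
  }
  symptoms <- draw_tokens(sym_prob, .vb_symptoms)
  triggers <- draw_tokens(trg_prob, .vb_triggers)
  sev_prob <- rbind(
    NORMAL = c(0.005, 0.045, 0.25, 0.70),
    MILD = c(0.03, 0.17, 0.45, 0.35),
    EXACERBATION = c(0.20, 0.45, 0.30, 0.05)
  )
  severity <- vapply(seq_len(ns), function(j) {
    sample(.vb_severity, 1, prob = sev_prob[sstate[j], ])
  }, character(1))
  resc_prob <- rbind(
    NORMAL = c(0.60, 0.06, 0.28, 0.06),
    MILD = c(0.35, 0.12, 0.48, 0.05),
    EXACERBATION = c(0.10, 0.18, 0.70, 0.02)
  )
  rescue <- vapply(seq_len(ns), function(j) {
    sample(.vb_rescue, 1, prob = resc_prob[sstate[j], ])
  }, character(1))

  hour <- 8L + (sample.int(12, ns, replace = TRUE) - 1L)
  minute <- sample.int(60, ns, replace = TRUE) - 1L
  session_time <- as.POSIXct(enrollment[si], tz = "UTC") +
    sday * 86400 + hour * 3600 + minute * 60

  sessions <- tibble::tibble(
    participant_id = ids[si],
    session_time = session_time,
    raw_score_1 = raw1,
    raw_score_2 = raw2,
    elicitation_pass_1 = e1$pass,
    elicitation_pass_2 = pass2,
    elicitation_attempts_1 = e1$attempts,
    elicitation_attempts_2 = att2,
    pef_1 = pef[, 1], pef_2 = pef[, 2], pef_3 = pef[, 3],
    wellbeing = wellbeing,
    symptoms = symptoms,
    triggers = triggers,
    severity_report = severity,
    rescue_use = rescue,
    .latent_state = .vb_states[sstate]
  ) |>
    dplyr::arrange(.data$participant_id, .data$session_time) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(session_id = sprintf("%s-s%04d", .data$participant_id,
                                       dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::relocate("session_id")

  latent_sessions <- sessions[, c("session_id", ".latent_state")]
  names(latent_sessions)[2] <- "state"
  sessions$.latent_state <- NULL

  # Monthly ACT driven by trailing 30-day state burden
  # (burden = fraction of mild days + 2 x fraction of exacerbation days).
  act_rows <- list()
  act_days <- unique(pmin(c(1, 30, 60, 90), days))
  for (d in act_days) {
    win <- max(1, d - 29):d
    burden <- rowMeans(states[, win, drop = FALSE] == 2L) +
      2 * rowMeans(states[, win, drop = FALSE] == 3L)
    done <- runif(n) < config$act_completion_prob
    score <- pmin(pmax(round(22 - 9 * burden + rnorm(n, 0, config$act_noise_sd)),
                       5), 25)
    act_rows[[length(act_rows) + 1]] <- tibble::tibble(
      participant_id = ids[done],
      act_date = enrollment[done] + d - 1,
      act_score = as.integer(score[done])
    )
  }
  act <- dplyr::bind_rows(act_rows)

  ds <- study_dataset(participants, sessions, act)
  attr(ds, "latent") <- list(
    participants = tibble::tibble(
      participant_id = ids, archetype = archetype,
      baseline_score = baseline, personal_best_lpm = pb
    ),
    sessions = latent_sessions,
    config = config
  )
  ds
}

#' Simulate the elicitation-check funnel
#'
#' Samples the three-attempt elicitation process for `n_sessions`
#' sessions of two voice samples each, with the configured per-attempt
#' failure probabilities, and tallies the funnel.
#'
#' @param config A [cohort_config()] (supplies
#'   `elicitation_fail_probs`; the seed is *not* set here, so wrap in
#'   [set.seed()] for reproducibility).
#' @param n_sessions Number of sessions (2 samples each).
#' @return List with `n_sessions`, `n_samples`, per-attempt counts
#'   (`first_attempts`, `first_failures`, `second_attempts`,
#'   `second_failures`, `third_attempts`, `third_failures`), and
#'   `sessions_by_passes` (sessions ending with 0/1/2 passing samples).
#' @export
simulate_qc_funnel <- function(config = cohort_config(), n_sessions) {
  stopifnot(n_sessions > 0)
  p <- config$elicitation_fail_probs
  k <- 2L * n_sessions
  f1 <- runif(k) < p[1]
  f2 <- f1 & (runif(k) < p[2])
  f3 <- f2 & (runif(k) < p[3])
  pass <- !f3
  pair <- matrix(pass, ncol = 2)
  n_pass <- rowSums(pair)
  list(
    n_sessions = n_sessions,
    n_samples = k,
    first_attempts = k,
    first_failures = sum(f1),
    second_attempts = sum(f1),
    second_failures = sum(f2),
    third_attempts = sum(f2),
    third_failures = sum(f3),
    sessions_by_passes = c(
      `0` = sum(n_pass == 0), `1` = sum(n_pass == 1), `2` = sum(n_pass == 2)
    )
  )
}
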
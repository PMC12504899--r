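# Engineered validation cohort (synthetic, deterministic).
#
# A counts-level dataset constructed so the deterministic pipeline stages
# reproduce known 2x2 risk tables end to end: 84 enrolled participants of
# whom 72 form the analysis cohort and 57 the normalized cohort; labeled
# sessions hit exact exacerbation/mild/normal cell counts in both the raw
# (threshold 65) and normalized (derived threshold) analyses, and ACT
# assessments hit exact control-level cells via value-pure session
# clusters placed so each +/-14-day window sees only its own cluster.
#
# Construction notes:
# - Group A (42 participants) has reference score 50 (median of their
#   normal-function scores); sessions valued 50/60/70 give normalized
#   scores 0/10/20. Group B (15) has reference 70; values 70/50 give 0/-20.
#   Any derived normalized threshold in (0, 10] therefore yields the same
#   banding; the composition below gives mean p70-p50 = 510/57 ~ 8.95.
# - Group C (15) participants have <5 normal sessions each (analysis
#   cohort only); group S (12) has 3 sessions each (enrollment only).
# - All sessions pass both QC gates (equal score pairs, all elicitation
#   passes), so completed = scored and the funnel is trivial by design.

# Round-robin split of `total` into `k` near-equal non-negative parts.
.rr_alloc <- function(total, k) {
  base <- total %/% k
  counts <- rep(base, k)
  extra <- total %% k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

# Session archetypes: score value determines band arithmetic; state
# determines (zone, wellbeing, PEF level).
.vc_session_kind <- function(state, score, flavor = "pef") {
  if (state == "NORMAL") {
    list(pef = 400, wellbeing = "GOOD")
  } else if (state == "EXACERBATION") {
    list(pef = 280, wellbeing = "NOT_GOOD")
  } else if (flavor == "pef") {      # mild via the PEF criterion
    list(pef = 300, wellbeing = "GOOD")
  } else {                            # mild via the well-being criterion
    list(pef = 400, wellbeing = "NOT_GOOD")
  }
}

#' Engineered validation cohort
#'
#' A deterministic synthetic `study_dataset` engineered at the counts
#' level so that running the full pipeline reproduces exact known risk
#' tables: raw-score exacerbation cells 167/704/57/581 (RR 2.15, 95% CI
#' 1.62-2.85) and mild cells 390/704/194/581 (RR 1.42), normalized
#' cells 124/382/65/883 (RR 3.57) and 186/382/293/883 (RR 1.31), and
#' ACT contrasts 61/18/50/26 (POOR vs WELL, RR 1.17) and 22/18/24/26
#' (NOT_WELL vs WELL, RR 1.15), with 201 of 234 assessments eligible.
#' Useful as an end-to-end regression harness: every stage (QC, PEF
#' personal best, zone classification, state labeling, reference-score
#' normalization, threshold derivation, banding, risk ratios) must be
#' correct for the cells to come out.
#'
#' @return A `study_dataset` (84 participants, 2165 sessions, 234 ACT
#'   assessments).
#' @export
validation_cohort <- function() {
  slot_center <- c(6, 34, 62, 88)
  enroll <- as.Date("2022-03-07")

  sessions <- list()
  acts <- list()

  add_sessions <- function(pid, slot, state, score, n, flavor = "pef") {
    if (n <= 0) return(invisible(NULL))
    kind <- .vc_session_kind(state, score, flavor)
    sessions[[length(sessions) + 1]] <<- tibble::tibble(
      participant_id = pid, slot = slot, state = state, score = score,
      pef = kind$pef, wellbeing = kind$wellbeing, n = n
    )
    invisible(NULL)
  }
  add_act <- function(pid, slot_day, level) {
    score <- c(POOR = 12L, NOT_WELL = 18L, WELL = 22L)[[level]]
    acts[[length(acts) + 1]] <<- tibble::tibble(
      participant_id = pid, day = slot_day, act_score = score
    )
    invisible(NULL)
  }

  # Level sequences for eligible ACT hosts, consumed in order.
  level_seq <- function(poor, notwell, well) {
    c(rep("POOR", poor), rep("NOT_WELL", notwell), rep("WELL", well))
  }
  lv <- list(
    A_HH = level_seq(30, 6, 11),   # A high-band clusters (value 70)
    A_LL = level_seq(32, 18, 20),  # A low-band clusters (value 50)
    B_HL = level_seq(21, 15, 6),   # B high-band clusters (value 70)
    B_LL = level_seq(8, 5, 5),     # B low-band clusters (value 50)
    C_H = level_seq(10, 1, 1),     # C high-band clusters (value 70)
    C_L = level_seq(10, 1, 1)      # C low-band clusters (value 60)
  )
  take <- function(key) {
    v <- lv[[key]][1]
    lv[[key]] <<- lv[[key]][-1]
    v
  }

  # ---- Group A: 42 participants, reference 50 --------------------------
  a_ids <- sprintf("A%02d", 1:42)
  # Normal-function composition per participant (50s strictly majority;
  # p70-p50 gap: 20 for P1-9, 10 for P10-42).
  a_n50 <- c(rep(10L, 9), rep(11L, 4), rep(11L, 15), rep(10L, 14))
  a_n60 <- c(rep(0L, 9), rep(4L, 4), rep(4L, 15), rep(4L, 14))
  a_n70 <- c(rep(9L, 9), rep(6L, 4), rep(5L, 15), rep(5L, 14))
  stopifnot(sum(a_n50) == 439, sum(a_n60) == 132, sum(a_n70) == 250)

  a_ex70 <- .rr_alloc(124, 42)
  a_ex50 <- .rr_alloc(40, 42)
  a_mi70 <- .rr_alloc(150, 42)
  a_mi50 <- .rr_alloc(73, 42)
  a_mi60 <- c(rep(0L, 9), .rr_alloc(36, 33))  # only participants with 60s

  for (i in 1:42) {
    pid <- a_ids[i]
    two_hh <- i <= 5                 # P1-5 host two high-band ACT clusters
    # Slot layout: value-pure clusters.
    if (i <= 9) {
      slots70 <- if (two_hh) c(1L, 2L) else 1L
      slots50 <- if (two_hh) c(3L, 4L) else c(2L, 3L)
      slot60 <- NA_integer_
    } else {
      slots70 <- 1L
      slots50 <- c(2L, 4L)
      slot60 <- 3L
    }
    spread <- function(n, slots) {
      if (length(slots) == 1) return(stats::setNames(n, slots))
      stats::setNames(.rr_alloc(n, length(slots)), slots)
    }
    n70 <- spread(a_n70[i] + a_ex70[i] + a_mi70[i], slots70)
    n50 <- spread(a_n50[i] + a_ex50[i] + a_mi50[i], slots50)

    # Distribute the state mix within each value: normals first.
    put_value <- function(per_slot, n_norm, n_ex, n_mi, score) {
      for (s in names(per_slot)) {
        room <- per_slot[[s]]
        k_n <- min(room, n_norm)
        add_sessions(pid, as.integer(s), "NORMAL", score, k_n)
        n_norm <- n_norm - k_n
        room <- room - k_n
        k_e <- min(room, n_ex)
        add_sessions(pid, as.integer(s), "EXACERBATION", score, k_e)
        n_ex <- n_ex - k_e
        room <- room - k_e
        add_sessions(pid, as.integer(s), "MILD", score, room)
      }
    }
    put_value(n70, a_n70[i], a_ex70[i], a_mi70[i], 70)
    put_value(n50, a_n50[i], a_ex50[i], a_mi50[i], 50)
    if (!is.na(slot60)) {
      add_sessions(pid, slot60, "NORMAL", 60, a_n60[i])
      add_sessions(pid, slot60, "MILD", 60, a_mi60[i])
    }

    # Eligible ACTs: high-band on 70-clusters, low-band on 50-clusters.
    for (s in slots70) add_act(pid, slot_center[s], take("A_HH"))
    n_ll <- if (i <= 5) 2L else if (i <= 9) 2L else if (i <= 28) 2L else 1L
    for (s in slots50[seq_len(n_ll)]) {
      add_act(pid, slot_center[s], take("A_LL"))
    }
  }

  # ---- Group B: 15 participants, reference 70 --------------------------
  b_ids <- sprintf("B%02d", 1:15)
  b_norm <- .rr_alloc(444, 15)
  b_ex70 <- .rr_alloc(13, 15)
  b_ex50 <- .rr_alloc(12, 15)
  b_mi70 <- .rr_alloc(180, 15)
  b_mi50_extra <- .rr_alloc(40 - 2 * 3, 12)   # B13-15 take 2 extra each
  for (i in 1:15) {
    pid <- b_ids[i]
    three_hl <- i <= 12
    slots70 <- if (three_hl) c(1L, 2L, 3L) else c(1L, 2L)
    slots50 <- if (three_hl) 4L else c(3L, 4L)
    mi50 <- if (three_hl) b_mi50_extra[i] else 2L

    n70 <- stats::setNames(.rr_alloc(b_norm[i] + b_ex70[i] + b_mi70[i],
                                     length(slots70)), slots70)
    n50 <- stats::setNames(.rr_alloc(b_ex50[i] + mi50, length(slots50)),
                           slots50)
    put_value <- function(per_slot, n_norm, n_ex, n_mi, score) {
      for (s in names(per_slot)) {
        room <- per_slot[[s]]
        k_n <- min(room, n_norm)
        add_sessions(pid, as.integer(s), "NORMAL", score, k_n)
        n_norm <- n_norm - k_n
        room <- room - k_n
        k_e <- min(room, n_ex)
        add_sessions(pid, as.integer(s), "EXACERBATION", score, k_e)
        n_ex <- n_ex - k_e
        room <- room - k_e
        add_sessions(pid, as.integer(s), "MILD", score, room)
      }
    }
    put_value(n70, b_norm[i], b_ex70[i], b_mi70[i], 70)
    put_value(n50, 0L, b_ex50[i], mi50, 50)

    for (s in slots70) add_act(pid, slot_center[s], take("B_HL"))
    for (s in slots50) add_act(pid, slot_center[s], take("B_LL"))
  }

  # ---- Group C: 15 participants, analysis cohort only ------------------
  c_ids <- sprintf("C%02d", 1:15)
  c_ex70 <- .rr_alloc(30, 15)
  c_ex60 <- .rr_alloc(5, 15)
  c_mi70 <- .rr_alloc(60, 15)
  c_mi60 <- .rr_alloc(45, 15)
  for (i in 1:15) {
    pid <- c_ids[i]
    # Slot 1: 70-valued cluster; slot 2: 60-valued cluster.
    add_sessions(pid, 1L, "NORMAL", 70, if (i <= 10) 1L else 0L)
    add_sessions(pid, 1L, "EXACERBATION", 70, c_ex70[i])
    add_sessions(pid, 1L, "MILD", 70, c_mi70[i], flavor = "wellbeing")
    add_sessions(pid, 2L, "NORMAL", 60, if (i >= 6) 1L else 0L)
    add_sessions(pid, 2L, "EXACERBATION", 60, c_ex60[i])
    add_sessions(pid, 2L, "MILD", 60, c_mi60[i], flavor = "wellbeing")

    if (i <= 9) {
      add_act(pid, slot_center[1], take("C_H"))
      add_act(pid, slot_center[2], take("C_L"))
    } else if (i <= 12) {
      add_act(pid, slot_center[1], take("C_H"))
    } else {
      add_act(pid, slot_center[2], take("C_L"))
    }
    if (i <= 3 || i >= 10) {   # 9 ineligible assessments, empty windows
      acts[[length(acts) + 1]] <- tibble::tibble(
        participant_id = pid, day = 88, act_score = 18L
      )
    }
  }

  # ---- Group S: 12 enrollment-only participants ------------------------
  s_ids <- sprintf("S%02d", 1:12)
  for (pid in s_ids) {
    add_sessions(pid, 1L, "NORMAL", 60, 3L)
    acts[[length(acts) + 1]] <- tibble::tibble(
      participant_id = pid, day = c(48, 88), act_score = 18L
    )
  }

  spec <- dplyr::bind_rows(sessions)
  # Sanity: engineered cell totals (analysis cohort = A+B+C).
  abc <- spec[substr(spec$participant_id, 1, 1) != "S", ]
  tot <- function(st, sc) sum(abc$n[abc$state == st & abc$score %in% sc])
  stopifnot(
    tot("EXACERBATION", 70) == 167, tot("EXACERBATION", c(50, 60)) == 57,
    tot("MILD", 70) == 390, tot("MILD", c(50, 60)) == 194,
    tot("NORMAL", 70) == 704, tot("NORMAL", c(50, 60)) == 581
  )

  # Expand the counts-level spec into session rows.
  expanded <- spec[rep(seq_len(nrow(spec)), spec$n), ]
  expanded <- expanded |>
    dplyr::group_by(.data$participant_id, .data$slot) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      day = slot_center[.data$slot] + ((.data$idx - 1L) %% 7L) - 3L,
      session_time = as.POSIXct(enroll, tz = "UTC") + .data$day * 86400 +
        (8L + (.data$idx %% 10L)) * 3600 + ((.data$idx * 13L) %% 60L) * 60
    )

  session_tbl <- tibble::tibble(
    participant_id = expanded$participant_id,
    session_time = expanded$session_time,
    raw_score_1 = expanded$score,
    raw_score_2 = expanded$score,
    elicitation_pass_1 = TRUE,
    elicitation_pass_2 = TRUE,
    elicitation_attempts_1 = 1L,
    elicitation_attempts_2 = 1L,
    pef_1 = expanded$pef,
    pef_2 = expanded$pef - 20,
    pef_3 = NA_real_,
    wellbeing = expanded$wellbeing,
    symptoms = ifelse(expanded$state == "EXACERBATION",
                      "shortness_of_breath;coughing",
                      ifelse(expanded$state == "MILD", "coughing", "")),
    triggers = ifelse(expanded$state == "NORMAL", "", "allergies"),
    severity_report = ifelse(expanded$state == "EXACERBATION", "moderate",
                             ifelse(expanded$state == "MILD", "mild",
                                    "none")),
    rescue_use = ifelse(expanded$state == "EXACERBATION",
                        "earlier_for_symptoms", "none_today")
  )

  act_tbl <- dplyr::bind_rows(acts) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      act_date = enroll + .data$day,
      act_score = as.integer(.data$act_score)
    )

  all_ids <- c(a_ids, b_ids, c_ids, s_ids)
  n <- length(all_ids)
  participants <- tibble::tibble(
    participant_id = all_ids,
    enrollment_date = enroll,
    sex = rep(c("female", "female", "female", "female", "male"),
              length.out = n),
    age_years = 25L + (seq_len(n) * 7L) %% 40L,
    ethnicity_hispanic = seq_len(n) %% 2 == 0,
    race = rep(c("black", "other", "white"), length.out = n),
    asthma_severity = rep(.vb_asthma_severity, length.out = n),
    comorbidity_count = (seq_len(n) * 3L) %% 6L,
    mental_health_any = seq_len(n) %% 3 == 0
  )

  study_dataset(participants, session_tbl, act_tbl)
}
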
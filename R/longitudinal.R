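# Within-participant change scores and cohort engagement metrics.

#' Respiratory-state transition change scores
#'
#' Pairs each participant's consecutive scored sessions (bridging over
#' unscored sessions; no maximum calendar gap by default) and summarizes
#' the final-score change per (initial state, final state) transition
#' type with mean, standard error (sample SD / sqrt(n)) and count.
#'
#' @param scored Labeled session tibble, any order (re-sorted by
#'   participant and time).
#' @param max_gap_days Optional sensitivity restriction: only pair
#'   sessions at most this many days apart (default `Inf`).
#' @return Tibble with `from_state`, `to_state`, `n_transitions`,
#'   `mean_change`, `se_change` (one row per observed transition type).
#' @export
transition_matrix <- function(scored, max_gap_days = Inf) {
  s <- scored |>
    dplyr::filter(!is.na(.data$final_score), !is.na(.data$state)) |>
    dplyr::arrange(.data$participant_id, .data$session_time) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      from_state = dplyr::lag(.data$state),
      change = .data$final_score - dplyr::lag(.data$final_score),
      gap_days = as.numeric(difftime(.data$session_time,
                                     dplyr::lag(.data$session_time),
                                     units = "days"))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$from_state), .data$gap_days <= max_gap_days)

  s |>
    dplyr::group_by(.data$from_state, to_state = .data$state) |>
    dplyr::summarise(
      n_transitions = dplyr::n(),
      mean_change = mean(.data$change),
      se_change = ifelse(dplyr::n() > 1,
                         sd(.data$change) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      from_state = factor(.data$from_state, levels = .vb_states),
      to_state = factor(.data$to_state, levels = .vb_states)
    ) |>
    dplyr::arrange(.data$from_state, .data$to_state)
}

#' Engagement and month-3 retention summary
#'
#' Counts every completed session (whether or not it passed QC --
#' engagement measures app use), buckets participants by total sessions
#' over the study (HIGH >= 52, MEDIUM 26--51, LOW 1--25), splits counts
#' into consecutive 30-day months anchored at each participant's
#' enrollment date, and reports month-3 retention: any use (>= 1
#' session) and consistent use (>= 8 sessions).
#'
#' @param ds A `study_dataset`.
#' @return List with `participants` (per-participant totals, group,
#'   monthly counts, retention flags) and `groups` (per-group and `All`
#'   aggregates: n, mean/SD sessions per month and total, retention
#'   counts and fractions).
#' @export
engagement_summary <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  sess <- ds$sessions |>
    dplyr::left_join(
      ds$participants[, c("participant_id", "enrollment_date")],
      by = "participant_id"
    ) |>
    dplyr::mutate(
      day = as.numeric(as.Date(.data$session_time, tz = "UTC") -
                         .data$enrollment_date),
      month = pmin(floor(.data$day / 30) + 1, 3)
    )

  monthly <- sess |>
    dplyr::count(.data$participant_id, .data$month) |>
    tidyr::pivot_wider(names_from = "month", values_from = "n",
                       names_prefix = "sessions_month_",
                       values_fill = 0L)
  for (col in paste0("sessions_month_", 1:3)) {
    if (!col %in% names(monthly)) monthly[[col]] <- 0L
  }

  participants <- ds$participants |>
    dplyr::select("participant_id") |>
    dplyr::left_join(monthly, by = "participant_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("sessions_month_"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(
      total_sessions = .data$sessions_month_1 + .data$sessions_month_2 +
        .data$sessions_month_3,
      group = dplyr::case_when(
        .data$total_sessions >= 52 ~ "HIGH",
        .data$total_sessions >= 26 ~ "MEDIUM",
        .data$total_sessions >= 1 ~ "LOW",
        TRUE ~ NA_character_
      ),
      retained_any_m3 = .data$sessions_month_3 >= 1,
      retained_consistent_m3 = .data$sessions_month_3 >= 8
    )

  aggregate <- function(df, label) {
    tibble::tibble(
      group = label,
      n_participants = nrow(df),
      mean_m1 = mean(df$sessions_month_1), sd_m1 = sd(df$sessions_month_1),
      mean_m2 = mean(df$sessions_month_2), sd_m2 = sd(df$sessions_month_2),
      mean_m3 = mean(df$sessions_month_3), sd_m3 = sd(df$sessions_month_3),
      mean_total = mean(df$total_sessions), sd_total = sd(df$total_sessions),
      n_retained_any_m3 = sum(df$retained_any_m3),
      frac_retained_any_m3 = mean(df$retained_any_m3),
      n_retained_consistent_m3 = sum(df$retained_consistent_m3),
      frac_retained_consistent_m3 = mean(df$retained_consistent_m3)
    )
  }
  groups <- dplyr::bind_rows(
    aggregate(participants, "All"),
    dplyr::bind_rows(lapply(c("HIGH", "MEDIUM", "LOW"), function(g) {
      df <- participants[!is.na(participants$group) &
                           participants$group == g, , drop = FALSE]
      if (nrow(df) == 0) return(NULL)
      aggregate(df, g)
    }))
  )
  list(participants = participants, groups = groups)
}

# Split a semicolon-joined token column into a logical matrix.
.token_matrix <- function(x, vocab) {
  out <- matrix(FALSE, length(x), length(vocab),
                dimnames = list(NULL, vocab))
  tokens <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  for (i in seq_along(tokens)) {
    hit <- intersect(tokens[[i]], vocab)
    if (length(hit) > 0) out[i, hit] <- TRUE
  }
  out
}

#' Descriptive symptom, trigger and rescue-use tables
#'
#' Cross-tabulates the patient-reported fields against respiratory
#' state for labeled sessions: symptom-count by reported severity,
#' per-symptom prevalence by state (with mean symptom types per
#' session), per-trigger prevalence by state, and rescue-inhaler use by
#' state.
#'
#' @param sessions Session tibble (carries the report fields).
#' @param scored Labeled session tibble (provides `state`).
#' @return List of tibbles: `symptom_severity`, `symptom_state`
#'   (long: `state`, `symptom`, `n`, `prevalence_pct`, plus
#'   `mean_symptom_types` per state), `trigger_state`, `rescue_state`.
#' @export
descriptive_tables <- function(sessions, scored) {
  joined <- dplyr::inner_join(
    scored[, c("session_id", "state")],
    sessions[, c("session_id", "symptoms", "triggers", "severity_report",
                 "rescue_use")],
    by = "session_id"
  )
  sym <- .token_matrix(joined$symptoms, .vb_symptoms)
  trg <- .token_matrix(joined$triggers, .vb_triggers)
  joined$n_symptoms <- rowSums(sym)

  symptom_severity <- joined |>
    dplyr::filter(!is.na(.data$severity_report)) |>
    dplyr::count(.data$n_symptoms, .data$severity_report) |>
    tidyr::pivot_wider(names_from = "severity_report", values_from = "n",
                       values_fill = 0L)

  state_n <- joined |>
    dplyr::count(.data$state, name = "n_state")
  long_tab <- function(mat, vocab) {
    dplyr::bind_rows(lapply(vocab, function(v) {
      joined |>
        dplyr::group_by(.data$state) |>
        dplyr::summarise(n = sum(mat[, v][dplyr::cur_group_rows()]),
                         .groups = "drop") |>
        dplyr::mutate(item = v)
    })) |>
      dplyr::left_join(state_n, by = "state") |>
      dplyr::mutate(prevalence_pct = 100 * .data$n / .data$n_state) |>
      dplyr::select("state", "item", "n", "n_state", "prevalence_pct") |>
      dplyr::arrange(.data$item, .data$state)
  }
  symptom_state <- long_tab(sym, .vb_symptoms)
  trigger_state <- long_tab(trg, .vb_triggers)

  mean_symptoms <- joined |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_symptom_types = mean(.data$n_symptoms),
                     .groups = "drop")

  rescue_state <- joined |>
    dplyr::filter(!is.na(.data$rescue_use)) |>
    dplyr::count(.data$rescue_use, .data$state) |>
    dplyr::group_by(.data$rescue_use) |>
    dplyr::mutate(pct_within_use = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  list(
    symptom_severity = symptom_severity,
    symptom_state = symptom_state,
    mean_symptoms_by_state = mean_symptoms,
    trigger_state = trigger_state,
    rescue_state = rescue_state
  )
}
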
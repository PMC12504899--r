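# Peak expiratory flow (PEF) pipeline: reading-level cleaning, personal
# best estimation, and relative-PEF zone classification.
#
# Personal best is estimated from the study data itself (no baseline
# period): per-session maxima are pooled, and the personal best is the
# highest maximum not exceeding their 95th percentile, which caps the
# influence of a single gross over-blow. Percentiles use linear
# interpolation between order statistics (stats::quantile type 7).

#' Best valid PEF reading of a session
#'
#' Readings above 1000 L/min are removed as device errors; the highest
#' remaining reading represents the session.
#'
#' @param readings Numeric vector of non-negative PEF readings (L/min);
#'   may be empty or contain `NA` (missing slots).
#' @return The highest valid reading, or `NA` if none remains.
#' @examples
#' session_max_pef(c(400, 410, 1200)) # 410
#' @export
session_max_pef <- function(readings) {
  readings <- readings[!is.na(readings)]
  if (any(readings < 0)) stop("PEF readings must be non-negative", call. = FALSE)
  readings <- readings[readings <= 1000]
  if (length(readings) == 0) return(NA_real_)
  max(readings)
}

#' Personal-best PEF from session maxima
#'
#' The personal best is the highest session maximum that does not exceed
#' the 95th percentile of all session maxima. With a constant series this
#' equals the common value; with a single gross outlier at the top the
#' outlier is excluded from candidacy.
#'
#' @param session_maxes Numeric vector of per-session maximum PEF values
#'   (L/min), `NA`s ignored.
#' @param prob Percentile cap (default 0.95), linear-interpolation
#'   convention.
#' @return The personal best in L/min.
#' @export
personal_best <- function(session_maxes, prob = 0.95) {
  v <- session_maxes[!is.na(session_maxes)]
  if (length(v) == 0) {
    stop("cannot estimate personal best: no valid PEF session maxima",
         call. = FALSE)
  }
  cap <- quantile(v, probs = prob, type = 7, names = FALSE)
  max(v[v <= cap])
}

#' Relative PEF and zone classification
#'
#' Expresses a session's best PEF as a percentage of the participant's
#' personal best and assigns the traffic-light zone: GREEN >= 80%,
#' YELLOW 50--79%, RED < 50%. Values below 20% or above 120% of personal
#' best are clinically implausible and flagged excluded (no zone).
#'
#' @param session_max Numeric vector of session maximum PEF (L/min).
#' @param personal_best Positive scalar (or vector) personal best (L/min).
#' @return Tibble with `relative_pct`, `zone` (`NA` when excluded or
#'   missing), and `excluded_reason` (`NA`, `"implausible_low"`,
#'   `"implausible_high"`, or `"missing"`).
#' @examples
#' relative_pef(c(320, 316, 70), 400)
#' @export
relative_pef <- function(session_max, personal_best) {
  if (any(personal_best <= 0, na.rm = TRUE)) {
    stop("personal best must be positive", call. = FALSE)
  }
  rel <- 100 * session_max / personal_best
  reason <- dplyr::case_when(
    is.na(rel) ~ "missing",
    rel < 20 ~ "implausible_low",
    rel > 120 ~ "implausible_high",
    TRUE ~ NA_character_
  )
  zone <- dplyr::case_when(
    !is.na(reason) ~ NA_character_,
    rel >= 80 ~ "GREEN",
    rel >= 50 ~ "YELLOW",
    TRUE ~ "RED"
  )
  tibble::tibble(
    relative_pct = ifelse(is.na(reason), rel, NA_real_),
    zone = zone,
    excluded_reason = reason
  )
}

#' Per-participant PEF profiles and session-level relative PEF
#'
#' Runs the full two-pass PEF pipeline over a session table: pass 1
#' cleans readings and estimates each participant's personal best from
#' all their session maxima; pass 2 expresses every session relative to
#' that personal best and classifies zones. Excluded sessions do not
#' trigger re-estimation of the personal best.
#'
#' @param sessions Session tibble with `session_id`, `participant_id`
#'   and reading columns `pef_1`, `pef_2`, `pef_3`.
#' @return List with `profiles` (one row per participant:
#'   `personal_best_lpm`, `n_sessions_used`, `n_error_readings`) and
#'   `relative` (one row per session with a usable reading:
#'   `session_id`, `participant_id`, `session_max_lpm`, `relative_pct`,
#'   `zone`, `excluded_reason`).
#' @export
pef_profiles <- function(sessions) {
  readings <- as.matrix(sessions[, c("pef_1", "pef_2", "pef_3")])
  if (any(readings < 0, na.rm = TRUE)) {
    stop("PEF readings must be non-negative", call. = FALSE)
  }
  n_error <- rowSums(readings > 1000, na.rm = TRUE)
  readings[readings > 1000] <- NA_real_
  smax <- suppressWarnings(apply(readings, 1, max, na.rm = TRUE))
  smax[!is.finite(smax)] <- NA_real_

  per_session <- tibble::tibble(
    session_id = sessions$session_id,
    participant_id = sessions$participant_id,
    session_max_lpm = smax,
    n_error_readings = n_error
  )

  profiles <- per_session |>
    dplyr::filter(!is.na(.data$session_max_lpm)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      personal_best_lpm = personal_best(.data$session_max_lpm),
      n_sessions_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      per_session |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(n_error_readings = sum(.data$n_error_readings),
                         .groups = "drop"),
      by = "participant_id"
    )

  relative <- per_session |>
    dplyr::filter(!is.na(.data$session_max_lpm)) |>
    dplyr::left_join(profiles[, c("participant_id", "personal_best_lpm")],
                     by = "participant_id")
  rel <- relative_pef(relative$session_max_lpm, relative$personal_best_lpm)
  relative <- dplyr::bind_cols(
    relative[, c("session_id", "participant_id", "session_max_lpm")], rel
  )

  list(profiles = profiles, relative = relative)
}
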
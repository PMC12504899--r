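# Respiratory-state labeling and per-participant score normalization.
#
# A session's state combines an objective criterion (relative PEF below
# 80% of personal best, i.e. YELLOW or RED zone) and a subjective one
# (well-being reported as NOT_GOOD or BAD): both met = EXACERBATION,
# neither = NORMAL, exactly one = MILD. The state never looks at the
# biomarker score, so downstream risk ratios are free of circularity.

#' Analysis configuration
#'
#' Collects the tunable thresholds of the analysis pipeline.
#'
#' @param raw_threshold High-risk boundary on the raw 0--100 score
#'   (default 65, the validated screening benchmark; scores >= 65 are
#'   high risk).
#' @param normalized_threshold High-risk boundary on normalized scores.
#'   `NULL` (default) means derive it from the data via
#'   [derive_normalized_threshold()].
#' @param consistency_threshold Two-sample QC agreement bound (default 10).
#' @param act_window_days Half-width of the ACT linkage window in days
#'   (default 14: a 4-week window centered on the assessment date).
#' @param min_sessions,min_normal Cohort floors (see
#'   [cohort_membership()]).
#' @param threshold_method How [derive_normalized_threshold()] computes
#'   the normalized threshold: `"percentile_gap"` (default; mean over
#'   participants of the 70th-minus-50th percentile gap of their
#'   normal-function scores) or `"pooled_p70"` (70th percentile of the
#'   pooled normalized normal-function scores).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(raw_threshold = 65, normalized_threshold = NULL,
                            consistency_threshold = 10, act_window_days = 14,
                            min_sessions = 4, min_normal = 5,
                            threshold_method = c("percentile_gap",
                                                 "pooled_p70")) {
  stopifnot(raw_threshold > 0, raw_threshold < 100,
            consistency_threshold >= 0, act_window_days >= 0)
  structure(
    list(
      raw_threshold = raw_threshold,
      normalized_threshold = normalized_threshold,
      consistency_threshold = consistency_threshold,
      act_window_days = act_window_days,
      min_sessions = min_sessions,
      min_normal = min_normal,
      threshold_method = match.arg(threshold_method)
    ),
    class = "analysis_config"
  )
}

#' Classify respiratory state from PEF zone and well-being
#'
#' Total function over the zone-by-well-being grid: EXACERBATION when
#' the reduced-PEF criterion (YELLOW/RED) and the impaired-well-being
#' criterion (NOT_GOOD/BAD) are both met, NORMAL when neither is, MILD
#' when exactly one is.
#'
#' @param zone Character vector in `GREEN`, `YELLOW`, `RED`.
#' @param wellbeing Character vector in `GOOD`, `NOT_GOOD`, `BAD`.
#' @return Character vector in `NORMAL`, `MILD`, `EXACERBATION` (`NA`
#'   where either input is missing).
#' @examples
#' classify_state("YELLOW", "NOT_GOOD") # EXACERBATION
#' classify_state("GREEN", "BAD")       # MILD
#' @export
classify_state <- function(zone, wellbeing) {
  stopifnot(all(zone %in% c(.vb_zones, NA)),
            all(wellbeing %in% c(.vb_wellbeing, NA)))
  pef_crit <- zone %in% c("YELLOW", "RED")
  wb_crit <- wellbeing %in% c("NOT_GOOD", "BAD")
  out <- dplyr::case_when(
    is.na(zone) | is.na(wellbeing) ~ NA_character_,
    pef_crit & wb_crit ~ "EXACERBATION",
    !pef_crit & !wb_crit ~ "NORMAL",
    TRUE ~ "MILD"
  )
  out
}

#' Label scored sessions with relative PEF, zone and respiratory state
#'
#' Joins QC outcomes, the PEF pipeline output and the session table into
#' the labeled session table the risk analyses consume. Only sessions
#' that survived QC (`SCORED`) and carry a usable, plausible PEF reading
#' and a well-being response receive a label.
#'
#' @param sessions Session tibble from a `study_dataset`.
#' @param qc Output of [qc_pipeline()].
#' @param pef Output of [pef_profiles()].
#' @return Tibble with one row per labeled session: `session_id`,
#'   `participant_id`, `session_time`, `final_score`, `relative_pct`,
#'   `zone`, `wellbeing`, `state` (and `normalized_score`, all `NA`,
#'   filled by [normalize_scores()]).
#' @export
label_sessions <- function(sessions, qc, pef) {
  scored <- qc |>
    dplyr::filter(.data$status == "SCORED") |>
    dplyr::select("session_id", "participant_id", "session_time",
                  "final_score") |>
    dplyr::inner_join(
      pef$relative |>
        dplyr::filter(is.na(.data$excluded_reason)) |>
        dplyr::select("session_id", "relative_pct", "zone"),
      by = "session_id"
    ) |>
    dplyr::inner_join(sessions[, c("session_id", "wellbeing")],
                      by = "session_id") |>
    dplyr::filter(!is.na(.data$wellbeing))
  scored$state <- classify_state(scored$zone, scored$wellbeing)
  scored$normalized_score <- NA_real_
  scored
}

#' Per-participant reference scores
#'
#' A participant's reference score is the median of their final scores
#' over sessions labeled normal function, using all such sessions across
#' the study period (no baseline window, no rolling update). Only
#' participants at or above the normal-session floor are returned; the
#' 70th-minus-50th percentile gap of the same scores is reported for
#' threshold derivation.
#'
#' @param scored Labeled session tibble from [label_sessions()].
#' @param min_normal Minimum number of normal-function sessions
#'   (default 5).
#' @return Tibble with `participant_id`, `reference_score`,
#'   `n_normal_sessions`, `p70_minus_p50`.
#' @export
reference_scores <- function(scored, min_normal = 5) {
  scored |>
    dplyr::filter(.data$state == "NORMAL") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      reference_score = median(.data$final_score),
      n_normal_sessions = dplyr::n(),
      p70_minus_p50 = quantile(.data$final_score, 0.7, type = 7,
                               names = FALSE) -
        quantile(.data$final_score, 0.5, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_normal_sessions >= min_normal)
}

#' Subtract per-participant reference scores
#'
#' Adds `normalized_score = final_score - reference_score` for sessions
#' of participants with a defined reference; other sessions keep `NA`
#' (they are outside the normalized cohort).
#'
#' @param scored Labeled session tibble.
#' @param norms Output of [reference_scores()].
#' @return `scored` with `normalized_score` filled in.
#' @export
normalize_scores <- function(scored, norms) {
  scored |>
    dplyr::select(-dplyr::any_of("normalized_score")) |>
    dplyr::left_join(norms[, c("participant_id", "reference_score")],
                     by = "participant_id") |>
    dplyr::mutate(
      normalized_score = .data$final_score - .data$reference_score
    ) |>
    dplyr::select(-"reference_score")
}

#' Derive the normalized high-risk threshold
#'
#' Default (`"percentile_gap"`): the mean, across participants in the
#' normalized cohort, of the 70th-minus-50th percentile gap of their
#' normal-function scores. Because the reference score is the median,
#' this is the average distance from a participant's typical
#' normal-function score to the upper (70th percentile) edge of their
#' normal range, and it serves as the high-risk cut point on normalized
#' scores. The alternative `"pooled_p70"` formulation takes the 70th
#' percentile of the pooled normalized normal-function scores.
#'
#' @param norms Output of [reference_scores()].
#' @param scored Labeled sessions with `normalized_score`; required for
#'   `method = "pooled_p70"`.
#' @param method `"percentile_gap"` (default) or `"pooled_p70"`.
#' @return Scalar threshold on the normalized-score scale.
#' @export
derive_normalized_threshold <- function(norms, scored = NULL,
                                        method = c("percentile_gap",
                                                   "pooled_p70")) {
  method <- match.arg(method)
  if (method == "percentile_gap") {
    if (is.null(norms) || nrow(norms) == 0) {
      stop("cannot derive threshold: no participants with a reference score",
           call. = FALSE)
    }
    return(mean(norms$p70_minus_p50))
  }
  if (is.null(scored)) {
    stop("method 'pooled_p70' needs the normalized session table",
         call. = FALSE)
  }
  pool <- scored$normalized_score[scored$state == "NORMAL" &
                                    !is.na(scored$normalized_score)]
  if (length(pool) == 0) {
    stop("cannot derive threshold: no normalized normal-function sessions",
         call. = FALSE)
  }
  quantile(pool, 0.7, type = 7, names = FALSE)
}

#' Assign the high/low risk band
#'
#' @param score Numeric vector of (raw or normalized) scores.
#' @param threshold Band boundary; scores at or above it are `HIGH`.
#' @return Character vector `HIGH`/`LOW` (`NA` preserved).
#' @examples
#' risk_band(c(64.99, 65), 65) # "LOW" "HIGH"
#' @export
risk_band <- function(score, threshold) {
  ifelse(is.na(score), NA_character_,
         ifelse(score >= threshold, "HIGH", "LOW"))
}

#' Zone-by-well-being cross-tabulation
#'
#' Counts labeled sessions over the 3x3 grid of PEF zone and well-being
#' response, with row/column/grand totals and percentages of the grand
#' total. The implied state totals (via [classify_state()]) partition
#' the grand total.
#'
#' @param scored Labeled session tibble with `zone` and `wellbeing`.
#' @return List of class `vb_crosstab`: `counts` and `pct` (3x3
#'   matrices, zones in rows), `row_totals`, `col_totals`, `grand_total`,
#'   and `state_counts` (named NORMAL/MILD/EXACERBATION totals).
#' @export
crosstab_zone_wellbeing <- function(scored) {
  counts <- table(factor(scored$zone, levels = .vb_zones),
                  factor(scored$wellbeing, levels = .vb_wellbeing))
  counts <- unclass(counts)
  grand <- sum(counts)
  grid <- expand.grid(zone = .vb_zones, wellbeing = .vb_wellbeing,
                      stringsAsFactors = FALSE)
  state_of_cell <- classify_state(grid$zone, grid$wellbeing)
  state_counts <- vapply(.vb_states, function(s) {
    sum(counts[cbind(grid$zone[state_of_cell == s],
                     grid$wellbeing[state_of_cell == s])])
  }, numeric(1))
  structure(
    list(
      counts = counts,
      pct = if (grand > 0) 100 * counts / grand else counts * 0,
      row_totals = rowSums(counts),
      col_totals = colSums(counts),
      grand_total = grand,
      state_counts = state_counts
    ),
    class = "vb_crosstab"
  )
}

#' @export
print.vb_crosstab <- function(x, ...) {
  cat("Zone x well-being cross-tab (n =", x$grand_total, ")\n")
  disp <- cbind(x$counts, Total = x$row_totals)
  disp <- rbind(disp, Total = c(x$col_totals, x$grand_total))
  print(disp)
  cat("States: ", paste(names(x$state_counts), x$state_counts,
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
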
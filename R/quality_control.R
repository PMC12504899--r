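# Post-collection quality control: elicitation bookkeeping and two-sample
# score consistency. The acoustic elicitation criteria are proprietary and
# applied on-device; this module consumes the recorded pass/fail flags.

#' Two-sample score consistency gate
#'
#' Accepts a session's pair of vocal-biomarker scores only if they agree
#' within `threshold` points, returning their arithmetic mean as the
#' session's final score; otherwise returns `NA` (rejected). The
#' agreement check is inclusive: a difference of exactly `threshold`
#' points is accepted.
#'
#' @param s1,s2 Numeric vectors of paired raw scores in \[0, 100\].
#' @param threshold Maximum absolute score difference (default 10).
#' @return Numeric vector: `(s1 + s2) / 2` where `|s1 - s2| <= threshold`,
#'   `NA` otherwise.
#' @examples
#' apply_two_sample_scoring(60, 65) # 62.5
#' apply_two_sample_scoring(60, 71) # NA, rejected
#' @export
apply_two_sample_scoring <- function(s1, s2, threshold = 10) {
  ok <- !is.na(s1) & !is.na(s2)
  if (any(s1[ok] < 0 | s1[ok] > 100 | s2[ok] < 0 | s2[ok] > 100)) {
    stop("raw scores must lie in [0, 100]", call. = FALSE)
  }
  out <- rep(NA_real_, max(length(s1), length(s2)))
  accept <- ok & abs(s1 - s2) <= threshold
  out[accept] <- (s1[accept] + s2[accept]) / 2
  out
}

#' Quality-control pipeline over study sessions
#'
#' Applies both quality gates to every session: a session must carry two
#' elicitation-passing raw scores (`FAIL_ELICITATION` otherwise), and the
#' two scores must agree within the consistency threshold
#' (`FAIL_CONSISTENCY` otherwise). Surviving sessions are `SCORED` with
#' `final_score` equal to the mean of the two raw scores.
#'
#' @param sessions Session tibble (from a `study_dataset`).
#' @param consistency_threshold Maximum score disagreement (default 10).
#' @return Tibble with one row per session: `session_id`,
#'   `participant_id`, `session_time`, `status` (one of `SCORED`,
#'   `FAIL_ELICITATION`, `FAIL_CONSISTENCY`), `final_score` (`NA` unless
#'   `SCORED`).
#' @export
qc_pipeline <- function(sessions, consistency_threshold = 10) {
  stopifnot(all(c("raw_score_1", "raw_score_2", "elicitation_pass_1",
                  "elicitation_pass_2") %in% names(sessions)))
  dual_pass <- !is.na(sessions$elicitation_pass_1) &
    !is.na(sessions$elicitation_pass_2) &
    sessions$elicitation_pass_1 & sessions$elicitation_pass_2 &
    !is.na(sessions$raw_score_1) & !is.na(sessions$raw_score_2)

  final <- rep(NA_real_, nrow(sessions))
  final[dual_pass] <- apply_two_sample_scoring(
    sessions$raw_score_1[dual_pass], sessions$raw_score_2[dual_pass],
    threshold = consistency_threshold
  )
  status <- dplyr::case_when(
    !dual_pass ~ "FAIL_ELICITATION",
    is.na(final) ~ "FAIL_CONSISTENCY",
    TRUE ~ "SCORED"
  )
  tibble::tibble(
    session_id = sessions$session_id,
    participant_id = sessions$participant_id,
    session_time = sessions$session_time,
    status = status,
    final_score = final
  )
}

#' State balance of quality-control exclusions
#'
#' Checks whether the quality gates excluded sessions unevenly across
#' respiratory states, which would bias downstream prevalence ratios.
#' States here are assigned from peak-flow zone and well-being alone
#' (available whether or not a session was scored), so excluded sessions
#' can be labeled too.
#'
#' @param outcomes Output of [qc_pipeline()].
#' @param labels Tibble with `session_id` and `state` for every session
#'   with a usable peak-flow reading and well-being response.
#' @return List with `by_state` (per-state counts and exclusion fractions
#'   per gate), `statistic` and `p_value` from a chi-square homogeneity
#'   test of QC status across states (statistic 0 / p 1 when nothing was
#'   excluded).
#' @export
qc_state_balance <- function(outcomes, labels) {
  joined <- dplyr::inner_join(outcomes, labels[, c("session_id", "state")],
                              by = "session_id")
  by_state <- joined |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_fail_elicitation = mean(.data$status == "FAIL_ELICITATION"),
      frac_fail_consistency = mean(.data$status == "FAIL_CONSISTENCY"),
      frac_scored = mean(.data$status == "SCORED"),
      .groups = "drop"
    )

  tab <- table(factor(joined$state, levels = .vb_states),
               factor(joined$status,
                      levels = c("SCORED", "FAIL_ELICITATION",
                                 "FAIL_CONSISTENCY")))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stat <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  list(by_state = by_state, statistic = stat, p_value = p)
}
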
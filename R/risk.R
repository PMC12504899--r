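# Prevalence risk ratios with log-scale (Katz) confidence intervals.
#
# The estimand is the ratio of event prevalence between the high and low
# biomarker bands, where prevalence is event / (event + reference) and
# the third state is excluded from the table entirely. The unit of
# analysis is the session (for ACT contrasts, the assessment), pooled
# across participants without clustering adjustment.

#' Construct a 2x2 prevalence table
#'
#' @param event_high,nonevent_high Event and reference-state counts in
#'   the high band.
#' @param event_low,nonevent_low Event and reference-state counts in the
#'   low band.
#' @param event,reference Labels for the two compared outcomes.
#' @param bands Band labels (default `HIGH`, `LOW`).
#' @return A list of class `two_by_two`.
#' @export
two_by_two <- function(event_high, nonevent_high, event_low, nonevent_low,
                       event = "event", reference = "reference",
                       bands = c("HIGH", "LOW")) {
  counts <- c(event_high, nonevent_high, event_low, nonevent_low)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all four cell counts must be non-negative", call. = FALSE)
  }
  structure(
    list(
      event_high = event_high, nonevent_high = nonevent_high,
      event_low = event_low, nonevent_low = nonevent_low,
      event = event, reference = reference, bands = bands
    ),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$event_high, x$event_low, x$nonevent_high, x$nonevent_low),
              nrow = 2, dimnames = list(x$bands, c(x$event, x$reference)))
  print(m)
  invisible(x)
}

#' Prevalence risk ratio with log-scale confidence interval
#'
#' Computes the risk (prevalence) ratio between the high and low bands
#' of a [two_by_two()] table, with the Katz log-method confidence
#' interval `exp(log RR +/- z * SE)`, where
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` for event cells `a`, `c`
#' and band totals `a+b`, `c+d`, and a two-sided normal p-value for
#' `log RR / SE` against RR = 1.
#'
#' @param table A `two_by_two`.
#' @param alpha Two-sided significance level (default 0.05, i.e. 95% CI).
#' @param correction Add 0.5 to every cell before estimation (off by
#'   default). Without it, a zero event cell is an error directing the
#'   caller here, rather than a silently corrected estimate.
#' @return List of class `risk_ratio_result`: `rr`, `ci_low`, `ci_high`,
#'   `p_value`, `se_log`, `alpha`, `table`.
#' @examples
#' risk_ratio(two_by_two(167, 704, 57, 581)) # RR 2.15, CI 1.62-2.85
#' @export
risk_ratio <- function(table, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$event_high
  b <- table$nonevent_high
  c_ <- table$event_low
  d <- table$nonevent_low
  if (correction) {
    a <- a + 0.5
    b <- b + 0.5
    c_ <- c_ + 0.5
    d <- d + 0.5
  }
  if (a == 0 || c_ == 0 || (a + b) == 0 || (c_ + d) == 0) {
    stop(
      "zero event cell or empty band: the risk ratio is undefined; ",
      "rerun with correction = TRUE to add 0.5 to every cell",
      call. = FALSE
    )
  }
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  z <- qnorm(1 - alpha / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  p <- if (se == 0) {
    if (rr == 1) 1 else 0
  } else {
    2 * pnorm(-abs(log(rr) / se))
  }
  structure(
    list(rr = rr, ci_low = ci[1], ci_high = ci[2], p_value = p,
         se_log = se, alpha = alpha, table = table),
    class = "risk_ratio_result"
  )
}

#' @export
print.risk_ratio_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "%s vs %s: RR %.2f (%.0f%% CI %.2f-%.2f), p %s\n",
    x$table$event, x$table$reference, x$rr, 100 * (1 - x$alpha),
    x$ci_low, x$ci_high,
    ifelse(x$p_value < 0.001, "<.001", sprintf("%.3g", x$p_value))
  ))
  cat(sprintf(
    "  cells [%s: %d/%d, %s: %d/%d] (event/reference)\n",
    x$table$bands[1], x$table$event_high, x$table$nonevent_high,
    x$table$bands[2], x$table$event_low, x$table$nonevent_low
  ))
  invisible(x)
}

# Internal: build an event-vs-NORMAL 2x2 from labeled sessions.
.state_table <- function(scored, event_state, score_col, threshold) {
  keep <- scored[scored$state %in% c(event_state, "NORMAL") &
                   !is.na(scored[[score_col]]), , drop = FALSE]
  band <- risk_band(keep[[score_col]], threshold)
  is_event <- keep$state == event_state
  two_by_two(
    event_high = sum(is_event & band == "HIGH"),
    nonevent_high = sum(!is_event & band == "HIGH"),
    event_low = sum(is_event & band == "LOW"),
    nonevent_low = sum(!is_event & band == "LOW"),
    event = event_state, reference = "NORMAL"
  )
}

#' Risk ratios for respiratory states
#'
#' Builds the EXACERBATION-vs-NORMAL and MILD-vs-NORMAL prevalence
#' tables (the third state is excluded from each) by banding sessions
#' at the raw or normalized threshold, and estimates both risk ratios.
#'
#' @param scored Labeled session tibble (with `normalized_score` filled
#'   for the normalized cohort when `use_normalized = TRUE`).
#' @param config An [analysis_config()]. For the normalized analysis
#'   `config$normalized_threshold` must be set (the pipeline derives it
#'   via [derive_normalized_threshold()]).
#' @param use_normalized Band by normalized rather than raw scores.
#' @return Named list (`EXACERBATION`, `MILD`) of `risk_ratio_result`.
#' @export
state_risk_tables <- function(scored, config = analysis_config(),
                              use_normalized = FALSE) {
  if (use_normalized) {
    score_col <- "normalized_score"
    threshold <- config$normalized_threshold
    if (is.null(threshold)) {
      stop("config$normalized_threshold is not set; derive it first",
           call. = FALSE)
    }
  } else {
    score_col <- "final_score"
    threshold <- config$raw_threshold
  }
  lapply(
    setNames(c("EXACERBATION", "MILD"), c("EXACERBATION", "MILD")),
    function(ev) risk_ratio(.state_table(scored, ev, score_col, threshold))
  )
}

#' Link ACT assessments to time-averaged biomarker scores
#'
#' For each ACT assessment, averages the participant's session scores
#' within a window of `act_window_days` days on either side of the
#' assessment date (inclusive boundaries; default a centered 4-week
#' window), bands the average at the configured threshold, and assigns
#' the asthma-control level from the ACT score: WELL >= 20, NOT_WELL
#' 16--19, POOR <= 15. Assessments with an empty window are marked
#' ineligible.
#'
#' @param act ACT tibble (`participant_id`, `act_date`, `act_score`).
#' @param scored Labeled session tibble.
#' @param config An [analysis_config()].
#' @param use_normalized Average normalized instead of raw scores
#'   (restricts to sessions with a normalized score).
#' @return Tibble with one row per assessment: `participant_id`,
#'   `act_date`, `act_score`, `control_level`, `n_window`,
#'   `time_averaged_score`, `band`, `eligible`.
#' @export
act_linkage <- function(act, scored, config = analysis_config(),
                        use_normalized = FALSE) {
  score_col <- if (use_normalized) "normalized_score" else "final_score"
  threshold <- if (use_normalized) config$normalized_threshold else
    config$raw_threshold
  if (is.null(threshold)) {
    stop("config$normalized_threshold is not set; derive it first",
         call. = FALSE)
  }
  usable <- scored[!is.na(scored[[score_col]]),
                   c("participant_id", "session_time", score_col)]
  usable$session_date <- as.Date(usable$session_time, tz = "UTC")

  out <- act |>
    dplyr::left_join(
      usable, by = "participant_id", relationship = "many-to-many"
    ) |>
    dplyr::mutate(
      in_window = !is.na(.data$session_date) &
        abs(as.numeric(.data$session_date - .data$act_date)) <=
          config$act_window_days
    ) |>
    dplyr::group_by(.data$participant_id, .data$act_date, .data$act_score) |>
    dplyr::summarise(
      n_window = sum(.data$in_window),
      time_averaged_score = ifelse(
        sum(.data$in_window) > 0,
        mean(.data[[score_col]][.data$in_window]), NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      control_level = dplyr::case_when(
        .data$act_score >= 20 ~ "WELL",
        .data$act_score >= 16 ~ "NOT_WELL",
        TRUE ~ "POOR"
      ),
      band = risk_band(.data$time_averaged_score, threshold),
      eligible = .data$n_window > 0
    )
  dplyr::arrange(out, .data$participant_id, .data$act_date)
}

#' Risk ratios for asthma-control levels
#'
#' Prevalence ratios over eligible ACT assessments (not sessions), with
#' well-controlled asthma as the reference level: POOR-vs-WELL and
#' NOT_WELL-vs-WELL, each contrasting the high versus low band of the
#' time-averaged biomarker score.
#'
#' @param linkages Output of [act_linkage()].
#' @param alpha Significance level (default 0.05).
#' @return Named list (`POOR`, `NOT_WELL`) of `risk_ratio_result`.
#' @export
act_risk_tables <- function(linkages, alpha = 0.05) {
  el <- linkages[linkages$eligible, , drop = FALSE]
  build <- function(level) {
    keep <- el[el$control_level %in% c(level, "WELL"), , drop = FALSE]
    is_event <- keep$control_level == level
    tab <- two_by_two(
      event_high = sum(is_event & keep$band == "HIGH"),
      nonevent_high = sum(!is_event & keep$band == "HIGH"),
      event_low = sum(is_event & keep$band == "LOW"),
      nonevent_low = sum(!is_event & keep$band == "LOW"),
      event = level, reference = "WELL"
    )
    risk_ratio(tab, alpha = alpha)
  }
  list(POOR = build("POOR"), NOT_WELL = build("NOT_WELL"))
}

#' Stratified (subgroup) exacerbation risk ratios
#'
#' Computes the exacerbation-vs-normal risk ratio within participant
#' strata (e.g. demographic subgroups), flagging strata whose cell
#' counts leave the estimate undefined, and assessing between-stratum
#' differences by confidence-interval overlap.
#'
#' @param scored Labeled session tibble.
#' @param config An [analysis_config()].
#' @param strata Tibble mapping `participant_id` to a single `stratum`.
#' @param use_normalized Band by normalized scores.
#' @return List with `results` (tibble: `stratum`, `rr`, `ci_low`,
#'   `ci_high`, `p_value`, the four cells, `defined`) and `overlap`
#'   (logical matrix; `TRUE` where two strata's CIs overlap, `NA` when
#'   either is undefined).
#' @export
stratified_risk <- function(scored, config = analysis_config(), strata,
                            use_normalized = FALSE) {
  stopifnot(all(c("participant_id", "stratum") %in% names(strata)))
  if (anyDuplicated(strata$participant_id) > 0) {
    stop("each participant must map to exactly one stratum", call. = FALSE)
  }
  joined <- dplyr::inner_join(scored, strata, by = "participant_id")
  levels_ <- sort(unique(strata$stratum))
  score_col <- if (use_normalized) "normalized_score" else "final_score"
  thr <- if (use_normalized) config$normalized_threshold else
    config$raw_threshold
  rows <- lapply(levels_, function(s) {
    sub <- joined[joined$stratum == s, , drop = FALSE]
    tab <- .state_table(sub, "EXACERBATION", score_col, thr)
    res <- tryCatch(risk_ratio(tab), error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(
        stratum = s, rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, event_high = tab$event_high,
        nonevent_high = tab$nonevent_high, event_low = tab$event_low,
        nonevent_low = tab$nonevent_low, defined = FALSE
      )
    } else {
      tibble::tibble(
        stratum = s, rr = res$rr, ci_low = res$ci_low,
        ci_high = res$ci_high, p_value = res$p_value,
        event_high = res$table$event_high,
        nonevent_high = res$table$nonevent_high,
        event_low = res$table$event_low,
        nonevent_low = res$table$nonevent_low, defined = TRUE
      )
    }
  })
  results <- dplyr::bind_rows(rows)
  k <- nrow(results)
  overlap <- matrix(NA, k, k, dimnames = list(results$stratum,
                                              results$stratum))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (results$defined[i] && results$defined[j]) {
        overlap[i, j] <- results$ci_low[i] <= results$ci_high[j] &&
          results$ci_low[j] <= results$ci_high[i]
      }
    }
  }
  list(results = results, overlap = overlap)
}
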
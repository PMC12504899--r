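# End-to-end pipeline orchestration and reporting.

#' Run the full analysis pipeline
#'
#' Composes the analysis stages in order -- quality control, PEF
#' personal-best estimation and zone classification, respiratory-state
#' labeling, cohort definition, per-participant normalization and
#' threshold derivation, state and ACT risk tables, change-score
#' transitions, engagement metrics and descriptive tables -- and
#' optionally writes every stage output plus a markdown report to
#' `out_dir`. Deterministic given the inputs (no stage uses random
#' numbers); every reported estimate carries its underlying counts.
#'
#' Degenerate inputs do not abort the run: a risk table whose cells
#' leave the ratio undefined (e.g. zero exacerbations) is reported as
#' undefined with its cells preserved.
#'
#' @param ds A `study_dataset` (e.g. from [read_dataset()],
#'   [simulate_cohort()] or [validation_cohort()]).
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts and
#'   `report.md`.
#' @return List with elements `qc`, `pef`, `scored` (labeled and
#'   normalized sessions), `cohorts`, `norms`, `normalized_threshold`,
#'   `risk_raw`, `risk_normalized`, `act_raw`, `act_normalized`
#'   (each a list with `linkage` and `tables`), `crosstab`,
#'   `transitions`, `engagement`, `descriptives`, `funnel` (row-count
#'   deltas at every filter), `config`.
#' @export
run_pipeline <- function(ds, config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(ds, "study_dataset"), inherits(config, "analysis_config"))

  qc <- qc_pipeline(ds$sessions,
                    consistency_threshold = config$consistency_threshold)
  pef <- pef_profiles(ds$sessions)
  scored_all <- label_sessions(ds$sessions, qc, pef)

  cohorts <- cohort_membership(ds, scored_all,
                               min_sessions = config$min_sessions,
                               min_normal = config$min_normal)
  analysis_ids <- cohorts$participant_id[cohorts$analysis]
  scored <- scored_all[scored_all$participant_id %in% analysis_ids, ,
                       drop = FALSE]

  norms <- reference_scores(scored, min_normal = config$min_normal)
  scored <- normalize_scores(scored, norms)
  threshold <- config$normalized_threshold
  if (is.null(threshold)) {
    threshold <- tryCatch(
      derive_normalized_threshold(norms, scored,
                                  method = config$threshold_method),
      error = function(e) NA_real_
    )
  }
  cfg <- config
  cfg$normalized_threshold <- threshold

  try_tables <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(message = conditionMessage(e)), class = "vb_undefined")
    })
  }
  risk_raw <- try_tables(state_risk_tables(scored, cfg,
                                           use_normalized = FALSE))
  risk_norm <- if (is.na(threshold)) {
    structure(list(message = "no normalized threshold (empty normalized cohort)"),
              class = "vb_undefined")
  } else {
    try_tables(state_risk_tables(scored, cfg, use_normalized = TRUE))
  }

  # All assessments enter the linkage; those of participants outside the
  # analysis cohort have no scored sessions and fall out as ineligible.
  act_raw_link <- act_linkage(ds$act, scored, cfg, use_normalized = FALSE)
  act_raw_tab <- try_tables(act_risk_tables(act_raw_link))
  if (!is.na(threshold)) {
    act_norm_link <- act_linkage(ds$act, scored, cfg, use_normalized = TRUE)
    act_norm_tab <- try_tables(act_risk_tables(act_norm_link))
  } else {
    act_norm_link <- NULL
    act_norm_tab <- structure(list(message = "no normalized threshold"),
                              class = "vb_undefined")
  }

  crosstab <- crosstab_zone_wellbeing(scored)
  transitions <- transition_matrix(scored)
  engagement <- engagement_summary(ds)
  descriptives <- descriptive_tables(ds$sessions, scored)

  funnel <- tibble::tibble(
    stage = c("completed_sessions", "qc_scored", "labeled",
              "analysis_cohort_labeled", "normalized_scored"),
    n = c(nrow(ds$sessions), sum(qc$status == "SCORED"), nrow(scored_all),
          nrow(scored), sum(!is.na(scored$normalized_score)))
  )

  result <- list(
    qc = qc, pef = pef, scored = scored, scored_all = scored_all,
    cohorts = cohorts, norms = norms, normalized_threshold = threshold,
    risk_raw = risk_raw, risk_normalized = risk_norm,
    act_raw = list(linkage = act_raw_link, tables = act_raw_tab),
    act_normalized = list(linkage = act_norm_link, tables = act_norm_tab),
    crosstab = crosstab, transitions = transitions,
    engagement = engagement, descriptives = descriptives,
    funnel = funnel, config = cfg
  )

  if (!is.null(out_dir)) .write_report_bundle(result, ds, out_dir)
  result
}

# Serialize a risk table list (or vb_undefined) for JSON output.
.rr_json <- function(x) {
  if (inherits(x, "vb_undefined")) {
    return(list(undefined = TRUE, message = x$message))
  }
  lapply(x, function(r) list(
    rr = r$rr, ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
    alpha = r$alpha,
    cells = list(
      event_high = r$table$event_high, nonevent_high = r$table$nonevent_high,
      event_low = r$table$event_low, nonevent_low = r$table$nonevent_low
    ),
    event = r$table$event, reference = r$table$reference
  ))
}

.fmt_rr <- function(x) {
  if (inherits(x, "vb_undefined")) return(paste("undefined:", x$message))
  vapply(names(x), function(nm) {
    r <- x[[nm]]
    sprintf(
      "%s vs %s: RR %.2f (95%% CI %.2f-%.2f), p %s [cells %d/%d | %d/%d]",
      nm, r$table$reference, r$rr, r$ci_low, r$ci_high,
      ifelse(r$p_value < 0.001, "<.001", sprintf("%.2g", r$p_value)),
      r$table$event_high, r$table$nonevent_high,
      r$table$event_low, r$table$nonevent_low
    )
  }, character(1))
}

.write_report_bundle <- function(result, ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  w(result$qc, "qc_outcomes.csv")
  w(result$pef$profiles, "pef_profiles.csv")
  w(result$pef$relative, "relative_pef.csv")
  w(result$scored, "scored_sessions.csv")
  w(result$norms, "normalization.csv")
  w(result$act_raw$linkage, "act_linkage.csv")
  w(result$transitions, "transitions.csv")
  w(result$engagement$participants, "engagement.csv")
  w(result$cohorts, "cohorts.csv")
  w(result$funnel, "funnel.csv")

  jsonlite::write_json(
    list(
      raw = .rr_json(result$risk_raw),
      normalized = .rr_json(result$risk_normalized),
      act_raw = .rr_json(result$act_raw$tables),
      act_normalized = .rr_json(result$act_normalized$tables),
      normalized_threshold = result$normalized_threshold
    ),
    file.path(out_dir, "risk_tables.json"), auto_unbox = TRUE, digits = NA
  )

  co <- result$cohorts
  eligible <- result$act_raw$linkage
  lines <- c(
    "# Vocal-biomarker monitoring report", "",
    "## Cohorts",
    sprintf("- enrollment: %d", sum(co$enrollment)),
    sprintf("- analysis (>=%d sessions): %d", result$config$min_sessions,
            sum(co$analysis)),
    sprintf("- normalized (>=%d normal-function sessions): %d",
            result$config$min_normal, sum(co$normalized)), "",
    "## Session funnel",
    sprintf("- %s: %d", result$funnel$stage, result$funnel$n), "",
    "## Risk ratios (raw scores, analysis cohort)",
    paste0("- ", .fmt_rr(result$risk_raw)), "",
    sprintf("## Risk ratios (normalized scores, threshold %.2f)",
            result$normalized_threshold),
    paste0("- ", .fmt_rr(result$risk_normalized)), "",
    "## ACT contrasts (raw scores)",
    sprintf("- eligible assessments: %d of %d", sum(eligible$eligible),
            nrow(eligible)),
    paste0("- ", .fmt_rr(result$act_raw$tables)), "",
    "## ACT contrasts (normalized scores)",
    paste0("- ", .fmt_rr(result$act_normalized$tables)), "",
    "## Zone x well-being cross-tab",
    utils::capture.output(print(result$crosstab)), "",
    "## Transitions (mean change, n)",
    sprintf("- %s -> %s: %+.2f (n=%d)",
            result$transitions$from_state, result$transitions$to_state,
            result$transitions$mean_change,
            result$transitions$n_transitions), "",
    "## Engagement",
    sprintf("- %s: n=%d, total %.1f (SD %.1f), m3 any %.0f%%, m3 consistent %.0f%%",
            result$engagement$groups$group,
            result$engagement$groups$n_participants,
            result$engagement$groups$mean_total,
            result$engagement$groups$sd_total,
            100 * result$engagement$groups$frac_retained_any_m3,
            100 * result$engagement$groups$frac_retained_consistent_m3)
  )
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
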
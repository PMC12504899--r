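# Study data model: participants, app sessions, ACT assessments.
#
# All session-level tables in the package are keyed by `session_id`, a
# deterministic identifier assigned per participant in time order. The
# on-disk schema carries no session id; it is re-derived on read, so a
# write/read round trip is the identity.

.session_cols <- c(
  "participant_id", "session_time", "raw_score_1", "raw_score_2",
  "elicitation_pass_1", "elicitation_pass_2",
  "elicitation_attempts_1", "elicitation_attempts_2",
  "pef_1", "pef_2", "pef_3",
  "wellbeing", "symptoms", "triggers", "severity_report", "rescue_use"
)
.act_cols <- c("participant_id", "act_date", "act_score")
.participant_cols <- c(
  "participant_id", "enrollment_date", "sex", "age_years",
  "ethnicity_hispanic", "race", "asthma_severity", "comorbidity_count",
  "mental_health_any"
)

#' Assemble a study dataset
#'
#' Bundles the three longitudinal study tables into a validated
#' `study_dataset` object: one row per enrolled participant, one row per
#' completed app session, and one row per monthly Asthma Control Test
#' (ACT) assessment.
#'
#' @param participants Tibble with columns `participant_id`,
#'   `enrollment_date` (Date), `sex`, `age_years`, `ethnicity_hispanic`,
#'   `race`, `asthma_severity`, `comorbidity_count`, `mental_health_any`.
#' @param sessions Tibble of app sessions (see [read_dataset()] for the
#'   column set). A `session_id` column is assigned if absent.
#' @param act Tibble with `participant_id`, `act_date` (Date),
#'   `act_score` (integer in 5--25).
#' @return A `study_dataset`: a list with elements `participants`,
#'   `sessions`, `act`, ordered by participant and time.
#' @export
study_dataset <- function(participants, sessions, act) {
  participants <- tibble::as_tibble(participants)
  sessions <- tibble::as_tibble(sessions)
  act <- tibble::as_tibble(act)

  if (anyDuplicated(participants$participant_id) > 0) {
    stop("duplicate participant_id in participants table", call. = FALSE)
  }
  bad_ref <- setdiff(
    c(sessions$participant_id, act$participant_id),
    participants$participant_id
  )
  if (length(bad_ref) > 0) {
    stop(
      "unresolvable participant_id(s): ",
      paste(sort(unique(bad_ref)), collapse = ", "),
      call. = FALSE
    )
  }

  sessions <- dplyr::arrange(sessions, .data$participant_id, .data$session_time)
  if (!"session_id" %in% names(sessions)) {
    sessions <- sessions |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(
        session_id = sprintf("%s-s%04d", .data$participant_id,
                             dplyr::row_number())
      ) |>
      dplyr::ungroup() |>
      dplyr::relocate("session_id")
  }
  act <- dplyr::arrange(act, .data$participant_id, .data$act_date)
  participants <- dplyr::arrange(participants, .data$participant_id)

  structure(
    list(participants = participants, sessions = sessions, act = act),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  sessions:    ", nrow(x$sessions), "\n")
  cat("  ACT records: ", nrow(x$act), "\n")
  diag <- attr(x, "diagnostics")
  if (!is.null(diag) && nrow(diag) > 0) {
    cat("  rejected rows:", nrow(diag), "(see attr(., 'diagnostics'))\n")
  }
  invisible(x)
}

# Row-level validation. Returns list(keep = logical, diagnostics = tibble).
.validate_rows <- function(df, table, checks) {
  keep <- rep(TRUE, nrow(df))
  msgs <- list()
  for (field in names(checks)) {
    ok <- checks[[field]](df)
    bad <- which(!ok)
    if (length(bad) > 0) {
      keep[bad] <- FALSE
      msgs[[field]] <- tibble::tibble(
        table = table, row = bad, field = field,
        message = paste0("invalid ", field)
      )
    }
  }
  list(keep = keep, diagnostics = dplyr::bind_rows(msgs))
}

.check_cols <- function(df, needed, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(
      "schema error in ", path, ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

#' Read a study dataset from delimited text tables
#'
#' Reads the three comma-separated study tables, validates them row by
#' row, and returns a [study_dataset()]. Rows violating type or range
#' constraints (e.g. an unrecognized well-being string, a score outside
#' 0--100) are rejected and reported in the `diagnostics` attribute; a
#' missing required column or an unresolvable `participant_id` is an
#' error.
#'
#' @param session_path,act_path,participant_path Paths to `sessions.csv`,
#'   `act.csv` and `participants.csv` (UTF-8, header row; `session_time`
#'   ISO-8601; `symptoms`/`triggers` semicolon-joined tokens).
#' @return A `study_dataset` with a `diagnostics` attribute (tibble with
#'   columns `table`, `row`, `field`, `message`; zero rows if all rows
#'   validated).
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(session_path, act_path, participant_path) {
  for (p in c(session_path, act_path, participant_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }

  sessions <- readr::read_csv(
    session_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session_time = readr::col_datetime(format = ""),
      raw_score_1 = readr::col_double(),
      raw_score_2 = readr::col_double(),
      elicitation_pass_1 = readr::col_logical(),
      elicitation_pass_2 = readr::col_logical(),
      elicitation_attempts_1 = readr::col_integer(),
      elicitation_attempts_2 = readr::col_integer(),
      pef_1 = readr::col_double(),
      pef_2 = readr::col_double(),
      pef_3 = readr::col_double(),
      .default = readr::col_character()
    )
  )
  .check_cols(sessions, .session_cols, session_path)
  # empty token sets round-trip as "" (the empty field is NA to the parser)
  sessions$symptoms[is.na(sessions$symptoms)] <- ""
  sessions$triggers[is.na(sessions$triggers)] <- ""
  act <- readr::read_csv(
    act_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      act_date = readr::col_date(format = ""),
      act_score = readr::col_integer()
    )
  )
  .check_cols(act, .act_cols, act_path)
  participants <- readr::read_csv(
    participant_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      enrollment_date = readr::col_date(format = ""),
      age_years = readr::col_integer(),
      comorbidity_count = readr::col_integer(),
      ethnicity_hispanic = readr::col_logical(),
      mental_health_any = readr::col_logical(),
      .default = readr::col_character()
    )
  )
  .check_cols(participants, .participant_cols, participant_path)

  in_range <- function(x, lo, hi) is.na(x) | (x >= lo & x <= hi)
  token_ok <- function(x, vocab) {
    vapply(x, function(s) {
      if (is.na(s) || s == "") return(TRUE)
      all(strsplit(s, ";", fixed = TRUE)[[1]] %in% vocab)
    }, logical(1))
  }

  vs <- .validate_rows(sessions, "sessions", list(
    participant_id = function(d) !is.na(d$participant_id),
    session_time = function(d) !is.na(d$session_time),
    raw_score_1 = function(d) in_range(d$raw_score_1, 0, 100),
    raw_score_2 = function(d) in_range(d$raw_score_2, 0, 100),
    elicitation_attempts_1 = function(d) in_range(d$elicitation_attempts_1, 1, 3),
    elicitation_attempts_2 = function(d) in_range(d$elicitation_attempts_2, 1, 3),
    pef = function(d) {
      ok <- in_range(d$pef_1, 0, Inf) & in_range(d$pef_2, 0, Inf) &
        in_range(d$pef_3, 0, Inf)
      ok
    },
    wellbeing = function(d) d$wellbeing %in% .vb_wellbeing,
    symptoms = function(d) token_ok(d$symptoms, .vb_symptoms),
    severity_report = function(d) is.na(d$severity_report) |
      d$severity_report %in% .vb_severity,
    rescue_use = function(d) is.na(d$rescue_use) |
      d$rescue_use %in% .vb_rescue
  ))
  va <- .validate_rows(act, "act", list(
    participant_id = function(d) !is.na(d$participant_id),
    act_date = function(d) !is.na(d$act_date),
    act_score = function(d) !is.na(d$act_score) & in_range(d$act_score, 5, 25)
  ))
  vp <- .validate_rows(participants, "participants", list(
    participant_id = function(d) !is.na(d$participant_id),
    enrollment_date = function(d) !is.na(d$enrollment_date),
    age_years = function(d) !is.na(d$age_years) & d$age_years >= 18,
    sex = function(d) d$sex %in% c("female", "male"),
    asthma_severity = function(d) d$asthma_severity %in% .vb_asthma_severity,
    comorbidity_count = function(d) !is.na(d$comorbidity_count) &
      d$comorbidity_count >= 0
  ))

  ds <- study_dataset(
    participants = participants[vp$keep, , drop = FALSE],
    sessions = sessions[vs$keep, , drop = FALSE],
    act = act[va$keep, , drop = FALSE]
  )
  attr(ds, "diagnostics") <- dplyr::bind_rows(
    vs$diagnostics, va$diagnostics, vp$diagnostics
  )
  ds
}

#' Write a study dataset to delimited text tables
#'
#' Emits `sessions.csv`, `act.csv` and `participants.csv` in the schema
#' [read_dataset()] consumes. Column order and formatting are fixed, so
#' writing the same dataset twice produces byte-identical files and a
#' write/read/write cycle is stable.
#'
#' @param ds A `study_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "study_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sessions <- ds$sessions
  sessions$session_time <- format(sessions$session_time,
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  sessions <- sessions[, .session_cols]
  act <- ds$act[, .act_cols]
  participants <- ds$participants[, .participant_cols]

  paths <- c(
    sessions = file.path(out_dir, "sessions.csv"),
    act = file.path(out_dir, "act.csv"),
    participants = file.path(out_dir, "participants.csv")
  )
  # NA is written as the empty field; empty token sets are canonical ""
  # so that write -> read -> write is byte-stable.
  readr::write_csv(sessions, paths[["sessions"]], progress = FALSE, na = "")
  readr::write_csv(act, paths[["act"]], progress = FALSE, na = "")
  readr::write_csv(participants, paths[["participants"]], progress = FALSE,
                   na = "")
  invisible(paths)
}

#' Cohort membership flags
#'
#' Flags each enrolled participant's cohort membership: `enrollment`
#' (all participants), `analysis` (at least 4 completed study sessions,
#' counted before quality control), and `normalized` (analysis cohort
#' members with at least 5 sessions labeled normal function, the floor
#' for estimating a per-participant reference score).
#'
#' @param ds A `study_dataset`.
#' @param scored Labeled session tibble from [label_sessions()] (needs
#'   `participant_id` and `state`). May be `NULL`, in which case the
#'   `normalized` flag is `NA`.
#' @param min_sessions,min_normal Cohort floors (defaults 4 and 5).
#' @return Tibble with `participant_id`, `n_sessions`,
#'   `n_normal_sessions`, and logical flags `enrollment`, `analysis`,
#'   `normalized`. Flags are monotone: normalized implies analysis.
#' @export
cohort_membership <- function(ds, scored = NULL, min_sessions = 4,
                              min_normal = 5) {
  stopifnot(inherits(ds, "study_dataset"))
  counts <- ds$sessions |>
    dplyr::count(.data$participant_id, name = "n_sessions")
  out <- ds$participants |>
    dplyr::select("participant_id") |>
    dplyr::left_join(counts, by = "participant_id") |>
    dplyr::mutate(n_sessions = dplyr::coalesce(.data$n_sessions, 0L))

  if (is.null(scored)) {
    out$n_normal_sessions <- NA_integer_
  } else {
    normals <- scored |>
      dplyr::filter(.data$state == "NORMAL") |>
      dplyr::count(.data$participant_id, name = "n_normal_sessions")
    out <- out |>
      dplyr::left_join(normals, by = "participant_id") |>
      dplyr::mutate(
        n_normal_sessions = dplyr::coalesce(.data$n_normal_sessions, 0L)
      )
  }

  out |>
    dplyr::mutate(
      enrollment = TRUE,
      analysis = .data$n_sessions >= min_sessions,
      normalized = .data$analysis & .data$n_normal_sessions >= min_normal
    )
}
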
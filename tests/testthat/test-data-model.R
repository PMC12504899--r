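test_that("write/read round trip is the identity on a study dataset", {
  ds <- simulate_cohort(cohort_config(n_participants = 6, study_days = 30,
                                      seed = 11))
  dir1 <- withr::local_tempdir()
  paths1 <- write_dataset(ds, dir1)
  back <- read_dataset(paths1[["sessions"]], paths1[["act"]],
                       paths1[["participants"]])
  expect_equal(nrow(attr(back, "diagnostics")), 0)
  expect_equal(as.data.frame(back$participants),
               as.data.frame(ds$participants))
  expect_equal(as.data.frame(back$act), as.data.frame(ds$act))
  expect_equal(as.data.frame(back$sessions[, .vb_test_session_cols()]),
               as.data.frame(ds$sessions[, .vb_test_session_cols()]))

  # write -> read -> write is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- write_dataset(back, dir2)
  for (nm in names(paths1)) {
    expect_identical(readLines(paths1[[nm]]), readLines(paths2[[nm]]))
  }
})

test_that("invalid rows are rejected with row-level diagnostics", {
  dir <- withr::local_tempdir()
  ds <- mk_ds(mk_sessions("P1", 0:2))
  paths <- write_dataset(ds, dir)
  sess <- readr::read_csv(paths[["sessions"]], show_col_types = FALSE)
  sess$wellbeing[2] <- "FANTASTIC"
  readr::write_csv(sess, paths[["sessions"]])
  back <- read_dataset(paths[["sessions"]], paths[["act"]],
                       paths[["participants"]])
  expect_equal(nrow(back$sessions), 2)
  diag <- attr(back, "diagnostics")
  expect_equal(nrow(diag), 1)
  expect_equal(diag$field, "wellbeing")
  expect_equal(diag$row, 2L)
})

test_that("missing columns and unresolvable participants are errors", {
  dir <- withr::local_tempdir()
  ds <- mk_ds(mk_sessions("P1", 0:2))
  paths <- write_dataset(ds, dir)

  sess <- readr::read_csv(paths[["sessions"]], show_col_types = FALSE)
  readr::write_csv(sess[, setdiff(names(sess), "wellbeing")],
                   paths[["sessions"]])
  expect_error(
    read_dataset(paths[["sessions"]], paths[["act"]],
                 paths[["participants"]]),
    "wellbeing"
  )

  expect_error(
    study_dataset(mk_participants("P1"), mk_sessions("P9", 0:2), mk_act()),
    "P9"
  )
  expect_error(
    study_dataset(mk_participants(c("P1", "P1")),
                  mk_sessions("P1", 0:2), mk_act()),
    "duplicate"
  )
})

test_that("synthetic dataset from the simulator parses with no diagnostics", {
  ds <- simulate_cohort(cohort_config(n_participants = 10, study_days = 90,
                                      seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths[["sessions"]], paths[["act"]],
                       paths[["participants"]])
  expect_equal(nrow(attr(back, "diagnostics")), 0)
  expect_equal(nrow(back$sessions), nrow(ds$sessions))
})

test_that("cohort flags implement the 4-session and 5-normal floors", {
  # 57 participants qualify fully, 15 have >=4 sessions but <5 normals,
  # 12 have <4 sessions: 84 enrolled / 72 analysis / 57 normalized.
  ids_full <- sprintf("F%02d", 1:57)
  ids_few_norm <- sprintf("N%02d", 1:15)
  ids_small <- sprintf("S%02d", 1:12)
  sessions <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(ids_full, function(p) mk_sessions(p, 0:5))),
    dplyr::bind_rows(lapply(ids_few_norm, function(p) mk_sessions(p, 0:5))),
    dplyr::bind_rows(lapply(ids_small, function(p) mk_sessions(p, 0:2)))
  )
  ds <- mk_ds(sessions)
  scored <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(ids_full, function(p) {
      mk_scored(p, rep("NORMAL", 6), rep(60, 6))
    })),
    dplyr::bind_rows(lapply(ids_few_norm, function(p) {
      mk_scored(p, c(rep("NORMAL", 4), "MILD", "MILD"), rep(60, 6))
    })),
    dplyr::bind_rows(lapply(ids_small, function(p) {
      mk_scored(p, rep("NORMAL", 3), rep(60, 3))
    }))
  )
  flags <- cohort_membership(ds, scored)
  expect_equal(sum(flags$enrollment), 84)
  expect_equal(sum(flags$analysis), 72)
  expect_equal(sum(flags$normalized), 57)
  # monotone: normalized => analysis => enrollment
  expect_true(all(!flags$normalized | flags$analysis))
  expect_true(all(!flags$analysis | flags$enrollment))
})

test_that("cohort boundary cases: no sessions, and 4 sessions all normal", {
  sessions <- mk_sessions("P1", 0:3)
  ds <- study_dataset(mk_participants(c("P1", "P2")), sessions, mk_act())
  scored <- mk_scored("P1", rep("NORMAL", 4), rep(60, 4))
  flags <- cohort_membership(ds, scored)
  p1 <- flags[flags$participant_id == "P1", ]
  p2 <- flags[flags$participant_id == "P2", ]
  expect_true(p1$analysis)
  expect_false(p1$normalized) # 4 normal sessions < 5
  expect_true(p2$enrollment)
  expect_false(p2$analysis)

  # counts invariant to session order
  ds2 <- study_dataset(mk_participants(c("P1", "P2")),
                       sessions[rev(seq_len(nrow(sessions))), ], mk_act())
  expect_equal(cohort_membership(ds2, scored)$n_sessions, flags$n_sessions)
})
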
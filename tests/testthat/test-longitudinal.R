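test_that("transition cells summarize consecutive within-participant pairs", {
  scored <- mk_scored("P1", c("NORMAL", "EXACERBATION"), c(60, 66))
  tm <- transition_matrix(scored)
  expect_equal(nrow(tm), 1)
  expect_equal(as.character(tm$from_state), "NORMAL")
  expect_equal(as.character(tm$to_state), "EXACERBATION")
  expect_equal(tm$mean_change, 6)
  expect_equal(tm$n_transitions, 1)

  # constant scores: diagonal means are zero
  scored <- mk_scored("P2", rep("MILD", 6), rep(55, 6))
  tm <- transition_matrix(scored)
  expect_equal(tm$mean_change, 0)
  expect_equal(tm$n_transitions, 5)
})

test_that("total pairs and time-reversal antisymmetry hold", {
  set.seed(21)
  scored <- dplyr::bind_rows(lapply(sprintf("P%d", 1:6), function(p) {
    n <- sample(2:12, 1)
    mk_scored(p, sample(c("NORMAL", "MILD", "EXACERBATION"), n, TRUE),
              runif(n, 40, 80))
  }))
  tm <- transition_matrix(scored)
  per_p <- table(scored$participant_id)
  expect_equal(sum(tm$n_transitions), sum(pmax(per_p - 1, 0)))

  # reversing time transposes cells and negates means
  rev_scored <- scored |>
    dplyr::mutate(session_time = max(.data$session_time) -
                    as.numeric(.data$session_time - min(.data$session_time)))
  rtm <- transition_matrix(rev_scored)
  joined <- dplyr::inner_join(
    tm, rtm,
    by = c(from_state = "to_state", to_state = "from_state")
  )
  expect_equal(nrow(joined), nrow(tm))
  expect_equal(joined$mean_change.x, -joined$mean_change.y)
  expect_equal(joined$n_transitions.x, joined$n_transitions.y)
})

test_that("gap restriction drops long-gap pairs", {
  scored <- mk_scored("P1", rep("NORMAL", 3), c(60, 61, 62),
                      day = c(0, 2, 40))
  expect_equal(sum(transition_matrix(scored)$n_transitions), 2)
  expect_equal(sum(transition_matrix(scored, max_gap_days = 7)$n_transitions),
               1)
})

test_that("engagement groups use exact total-session boundaries", {
  sessions <- dplyr::bind_rows(
    mk_sessions("H1", 0:59),          # 60 -> HIGH
    mk_sessions("H2", 0:51),          # 52 -> HIGH boundary
    mk_sessions("M1", 0:50),          # 51 -> MEDIUM boundary
    mk_sessions("M2", 0:25),          # 26 -> MEDIUM boundary
    mk_sessions("L1", 0:24),          # 25 -> LOW boundary
    mk_sessions("L2", 0)              # 1 -> LOW
  )
  ds <- study_dataset(mk_participants(c("H1", "H2", "M1", "M2", "L1",
                                        "L2", "Z0")),
                      sessions, mk_act())
  eng <- engagement_summary(ds)
  p <- eng$participants
  grp <- setNames(p$group, p$participant_id)
  expect_equal(unname(grp[c("H1", "H2", "M1", "M2", "L1", "L2")]),
               c("HIGH", "HIGH", "MEDIUM", "MEDIUM", "LOW", "LOW"))
  expect_true(is.na(grp[["Z0"]]))

  # groups partition the participants with at least one session
  expect_equal(sum(!is.na(p$group)), 6)
})

test_that("month-3 retention uses 30-day enrollment-anchored blocks", {
  sessions <- dplyr::bind_rows(
    mk_sessions("A", 0:29),                 # month 1 only
    mk_sessions("B", c(0:9, 60:68))         # 9 sessions in month 3
  )
  ds <- mk_ds(sessions)
  p <- engagement_summary(ds)$participants
  a <- p[p$participant_id == "A", ]
  b <- p[p$participant_id == "B", ]
  expect_false(a$retained_any_m3)
  expect_equal(a$sessions_month_1, 30)
  expect_true(b$retained_any_m3)
  expect_true(b$retained_consistent_m3)
  expect_equal(b$sessions_month_3, 9)
})

test_that("descriptive tables compute per-state symptom prevalence", {
  # engineered: 1285 normal sessions, 304 with coughing -> 23.65%
  n_norm <- 1285
  sessions <- mk_sessions("P1", seq_len(n_norm + 100))
  sessions$session_id <- sprintf("s%d", seq_len(n_norm + 100))
  sessions$symptoms <- c(rep("coughing", 304), rep("", n_norm - 304),
                         rep("coughing;shortness_of_breath", 100))
  scored <- tibble::tibble(
    session_id = sessions$session_id,
    state = c(rep("NORMAL", n_norm), rep("EXACERBATION", 100))
  )
  d <- descriptive_tables(sessions, scored)
  cough_norm <- d$symptom_state[d$symptom_state$item == "coughing" &
                                  d$symptom_state$state == "NORMAL", ]
  expect_equal(cough_norm$n, 304)
  expect_equal(cough_norm$prevalence_pct, 100 * 304 / 1285, tolerance = 1e-6)
  m <- d$mean_symptoms_by_state
  expect_equal(m$mean_symptom_types[m$state == "EXACERBATION"], 2)

  # symptom-free input: zero prevalence everywhere
  sessions$symptoms <- ""
  d0 <- descriptive_tables(sessions, scored)
  expect_true(all(d0$symptom_state$n == 0))
  expect_true(all(d0$mean_symptoms_by_state$mean_symptom_types == 0))
})
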